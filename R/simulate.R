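#' Configuration for the synthetic corpus generator
#'
#' Defines a multi-sample, multi-organ single-cell count corpus with planted
#' ground truth: known sample sexes, a set of stable (housekeeping-like)
#' genes, organ-specific genes, cell-type cluster structure, and cells
#' constructed to violate each quality-control rule. The defaults describe
#' the reference corpus used throughout the package's tests: 8 main samples
#' (two per organ over four organs) of 250 cells each plus one under-sized
#' sample, 1000 genes, 4 cell types.
#'
#' @param n_samples number of full-size samples; assigned to `organs`
#'   round-robin, with sexes alternating male/female unless `sex_assignment`
#'   is given.
#' @param organs character vector of organ names.
#' @param cells_per_sample cells per full-size sample (violator cells are
#'   drawn from this quota).
#' @param n_genes total genes; must leave room for at least 300 background
#'   genes after the planted panels.
#' @param n_stable_genes planted stable genes (near-zero dropout, constant
#'   mean everywhere).
#' @param n_osg_per_organ planted organ-specific genes per organ (expressed
#'   only in their organ).
#' @param n_cell_types number of planted cell types; each gets 10 marker
#'   genes.
#' @param sex_assignment optional character vector (`"male"`/`"female"`) per
#'   sample.
#' @param nb_mean,nb_dispersion negative-binomial baseline mean and size for
#'   background genes.
#' @param dropout_rate constant Bernoulli dropout probability applied on top
#'   of the negative binomial for background genes. Most zeros come from the
#'   negative binomial itself (so, as in real data, detection tracks the
#'   per-type mean); raising this reaches the regime where most genes are
#'   zero in over 80% of cells.
#' @param mito_fraction_mean mean mitochondrial fraction of ordinary cells
#'   (Beta-distributed, clipped below the QC threshold).
#' @param n_outlier_cells cells planted with detected-gene counts far above
#'   their sample's mean + 3 SD.
#' @param n_low_complexity_cells cells planted with ~50 detected genes
#'   (below the 200-gene floor).
#' @param n_low_coding_cells cells planted with fewer than 7 detected
#'   protein-coding/miRNA genes but over 200 detected genes overall.
#' @param n_high_mito_cells cells planted with ~30% mitochondrial fraction.
#' @param n_small_samples extra samples planted with `small_sample_cells`
#'   cells (below the per-sample cell floor).
#' @param small_sample_cells cells in each under-sized sample.
#' @param species species tag; decides the Y-marker symbol (`SRY` for human,
#'   `Sry` otherwise).
#' @param seed integer seed; fixes the corpus bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8,
                       organs = c("brain", "liver", "lung", "kidney"),
                       cells_per_sample = 250,
                       n_genes = 1000,
                       n_stable_genes = 20,
                       n_osg_per_organ = 5,
                       n_cell_types = 4,
                       sex_assignment = NULL,
                       nb_mean = 3,
                       nb_dispersion = 3,
                       dropout_rate = 0.15,
                       mito_fraction_mean = 0.05,
                       n_outlier_cells = 5,
                       n_low_complexity_cells = 5,
                       n_low_coding_cells = 5,
                       n_high_mito_cells = 5,
                       n_small_samples = 1,
                       small_sample_cells = 2,
                       species = "human",
                       seed = 1) {
  if (length(organs) < 1L) stop_format("organs must be non-empty")
  if (is.null(sex_assignment)) {
    # alternate by organ block so every organ holds both sexes (chrY genes
    # must not look organ-specific)
    block <- (seq_len(n_samples) - 1L) %/% length(organs)
    sex_assignment <- ifelse(block %% 2L == 0L, "male", "female")
  }
  if (length(sex_assignment) != n_samples) {
    stop_format("sex_assignment must name a sex for each of %d samples", n_samples)
  }
  if (!all(sex_assignment %in% c("male", "female"))) {
    stop_format("sex_assignment entries must be 'male' or 'female'")
  }
  n_special <- n_stable_genes + (n_stable_genes %/% 4L + 1L) +
    n_osg_per_organ * length(organs) + 10L * n_cell_types + 5L + 20L + 10L
  if (n_genes < n_special + 300L) {
    stop_format("n_genes = %d too small: planted panels need %d genes plus >= 300 background genes",
                n_genes, n_special)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Counts follow a negative binomial per (cell type, gene) with
#' multiplicative Bernoulli dropout. Planted structure:
#' * stable genes: high expression, no dropout, identical mean in every
#'   cell — lowest zero-rates and lowest pseudo-bulk CV in the corpus; plus
#'   a small "near-stable" panel (mild type/organ modulation) forming the
#'   variable minority of the housekeeping reference list;
#' * organ-specific genes: moderate expression in their organ, exactly zero
#'   elsewhere;
#' * cell-type markers (10 per type) plus mild log-normal cell-type and
#'   organ modulation of background genes — cluster structure and
#'   pseudo-bulk variability;
#' * sex signal: the Y marker (SRY/Sry) and four other chrY genes at
#'   baseline mean in male samples, zero in female samples; 15 of 20 chrX
#'   genes are chrX-unique;
#' * mitochondrial counts allocated per cell from a Beta mixture (ordinary
#'   cells ~5%, planted high-mito cells ~30%);
#' * one planted violator roster per QC rule, each violator constructed to
#'   fail exactly its own rule, so staged removals can be checked exactly.
#'
#' Ordinary cells' detected-gene counts are clipped into a 2-SD band around
#' their sample mean so the only 3-SD outliers are the planted ones.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` ([cell_matrix()]), `annotation`
#'   ([gene_annotation()]), `samples` ([sample_metadata()]), and `truth`, a
#'   list with `sex_of_sample`, `stable_gene_symbols`, `osg_map`,
#'   `hkg_list` (3/4 planted-stable, 1/4 near-stable — a housekeeping-style
#'   reference), `cluster_of_cell`, and `qc_violations` (stage name ->
#'   cell ids).
#' @export
generate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  organs <- cfg$organs
  nO <- length(organs); nT <- cfg$n_cell_types
  y_marker <- if (identical(cfg$species, "human")) "SRY" else "Sry"

  ## ---- gene panel ---------------------------------------------------------
  stable <- sprintf("STAB%03d", seq_len(cfg$n_stable_genes))
  n_hkg_stable <- max(1L, round(cfg$n_stable_genes * 0.75))
  hkvar <- sprintf("HKV%02d", seq_len(cfg$n_stable_genes - n_hkg_stable))
  osg <- unlist(lapply(organs, function(o) {
    sprintf("OSG-%s-%02d", o, seq_len(cfg$n_osg_per_organ))
  }))
  osg_organ <- rep(organs, each = cfg$n_osg_per_organ)
  markers <- unlist(lapply(seq_len(nT), function(t) sprintf("MRK-T%d-%02d", t, 1:10)))
  marker_type <- rep(seq_len(nT), each = 10L)
  chry <- c(y_marker, sprintf("YG%02d", 1:4))
  chrx <- sprintf("XG%02d", 1:20)
  mito <- sprintf("MT-G%02d", 1:10)
  n_bg <- cfg$n_genes - length(stable) - length(hkvar) - length(osg) -
    length(markers) - length(chry) - length(chrx) - length(mito)
  bg <- sprintf("BG%04d", seq_len(n_bg))
  symbols <- c(stable, hkvar, osg, markers, chry, chrx, mito, bg)
  G <- length(symbols)

  kind <- c(rep("stable", length(stable)), rep("hkvar", length(hkvar)),
            rep("osg", length(osg)),
            rep("marker", length(markers)), rep("chrY", length(chry)),
            rep("chrX", length(chrx)), rep("mito", length(mito)),
            rep("bg", n_bg))
  autosomes <- paste0("chr", 1:19)
  chromosome <- ifelse(kind == "chrY", "chrY",
                ifelse(kind == "chrX", "chrX",
                ifelse(kind == "mito", "chrM",
                       sample(autosomes, G, replace = TRUE))))
  # background biotypes: mostly coding, with enough non-coding genes to host
  # the low-coding violators (which need > 200 detected non-coding genes)
  biotype <- rep("protein_coding", G)
  bg_idx <- which(kind == "bg")
  n_other <- ceiling(0.30 * n_bg)
  n_mirna <- ceiling(0.08 * n_bg)
  other_idx <- bg_idx[seq_len(n_other)]
  biotype[other_idx] <- "other"
  biotype[bg_idx[n_other + seq_len(n_mirna)]] <- "miRNA"
  ann <- gene_annotation(
    symbol = symbols, chromosome = chromosome, biotype = biotype,
    is_mitochondrial = kind == "mito",
    exonic_length_bp = sample(500:5000, G, replace = TRUE),
    is_chrX_unique = kind == "chrX" & seq_len(G) %in% which(kind == "chrX")[1:15])

  ## ---- per-gene expression parameters ------------------------------------
  base_mean <- rep(0, G)
  nb_size <- rep(cfg$nb_dispersion, G)
  dropout <- rep(cfg$dropout_rate, G)
  # stable genes mimic high-expression housekeeping genes: no dropout,
  # tight negative binomial, identical mean everywhere
  base_mean[kind == "stable"] <- 30; nb_size[kind == "stable"] <- 20
  dropout[kind == "stable"] <- 0
  # near-stable genes: like stable genes but with mild type/organ
  # modulation; the variable minority of the housekeeping reference
  base_mean[kind == "hkvar"] <- 30; nb_size[kind == "hkvar"] <- 20
  dropout[kind == "hkvar"] <- 0
  base_mean[kind == "osg"] <- 4; dropout[kind == "osg"] <- 0.25
  base_mean[kind == "marker"] <- 8; dropout[kind == "marker"] <- 0.2
  base_mean[kind == "chrY"] <- 5; nb_size[kind == "chrY"] <- 4
  dropout[kind == "chrY"] <- 0.3
  base_mean[kind == "chrX"] <- 5; nb_size[kind == "chrX"] <- 4
  dropout[kind == "chrX"] <- 0.3
  # background zeros arise mostly from the negative binomial (hence vary
  # with the per-type mean, as detection does in real data), with a smaller
  # constant dropout on top
  base_mean[kind == "bg"] <- pmin(pmax(
    exp(rnorm(n_bg, log(cfg$nb_mean), 0.5)), 1.5), 8)

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  organ_mult <- matrix(1, G, nO, dimnames = list(symbols, organs))
  mod_idx <- kind %in% c("bg", "chrX")
  organ_mult[mod_idx, ] <- clip(exp(matrix(rnorm(sum(mod_idx) * nO, 0, 0.25),
                                           ncol = nO)), 0.6, 5 / 3)
  # distinct major cell types differ across much of the transcriptome:
  # every background gene carries a log-normal per-type factor
  type_mult <- matrix(1, G, nT)
  type_mult[kind == "bg", ] <- clip(exp(matrix(rnorm(n_bg * nT, 0, 1.0),
                                               ncol = nT)), 0.25, 4)
  # housekeeping-style reference list: mostly genuinely stable genes plus a
  # minority of modestly variable members (as real HKG lists have); the
  # variable members get tempered type modulation
  type_mult[kind == "hkvar", ] <- exp(matrix(
    rnorm(sum(kind == "hkvar") * nT, 0, 0.25), ncol = nT))
  organ_mult[kind == "hkvar", ] <- exp(matrix(
    rnorm(sum(kind == "hkvar") * nO, 0, 0.1), ncol = nO))

  ## ---- samples and cells --------------------------------------------------
  n_main <- cfg$n_samples
  sample_ids <- sprintf("S%d", seq_len(n_main + cfg$n_small_samples))
  sample_organ <- c(organs[((seq_len(n_main) - 1L) %% nO) + 1L],
                    rep(organs[1], cfg$n_small_samples))
  sample_sex <- c(cfg$sex_assignment, rep("female", cfg$n_small_samples))
  sample_n <- c(rep(cfg$cells_per_sample, n_main),
                rep(cfg$small_sample_cells, cfg$n_small_samples))
  ncells <- sum(sample_n)
  cell_sample <- rep(sample_ids, sample_n)
  cell_organ <- rep(sample_organ, sample_n)
  cell_sex <- rep(sample_sex, sample_n)
  cell_type <- unlist(lapply(sample_n, function(n) {
    rep_len(seq_len(nT), n)                # identical composition everywhere
  }))
  cell_ids <- sprintf("c%05d-%s", seq_len(ncells), cell_sample)

  # violator placement: each violator class lives in its own full-size sample
  place <- function(n, sample_idx, used) {
    pool <- setdiff(which(cell_sample == sample_ids[sample_idx]), used)
    if (n > length(pool)) stop_format("sample %d too small for planted violators",
                                      sample_idx)
    sort(pool[seq_len(n)])
  }
  used <- integer(0)
  v_lowcx <- place(cfg$n_low_complexity_cells, 1L, used)
  used <- c(used, v_lowcx)
  v_lowcod <- place(cfg$n_low_coding_cells, min(2L, n_main), used)
  used <- c(used, v_lowcod)
  v_mito <- place(cfg$n_high_mito_cells, min(3L, n_main), used)
  used <- c(used, v_mito)
  v_out <- place(cfg$n_outlier_cells, min(4L, n_main), used)
  used <- c(used, v_out)
  v_small <- which(cell_sample %in% sample_ids[seq_len(cfg$n_small_samples) + n_main])
  is_violator <- seq_len(ncells) %in% c(used)

  ## ---- baseline counts ----------------------------------------------------
  counts <- matrix(0, ncells, G, dimnames = list(cell_ids, symbols))
  organ_col <- match(cell_organ, organs)
  for (o in seq_len(nO)) for (t in seq_len(nT)) {
    rows <- which(organ_col == o & cell_type == t)
    if (!length(rows)) next
    mu <- base_mean * organ_mult[, o] * type_mult[, t]
    mu[kind == "osg"] <- ifelse(osg_organ == organs[o], 4, 0)
    mu[kind == "marker"] <- ifelse(marker_type == t, 8, 0.8)
    nc <- length(rows)
    block <- matrix(rnbinom(nc * G, mu = rep(mu, each = nc),
                            size = rep(nb_size, each = nc)), nc, G)
    keep <- matrix(rbinom(nc * G, 1L, rep(1 - dropout, each = nc)), nc, G)
    counts[rows, ] <- block * keep
  }
  # sex signal: chrY genes are silent in female samples
  counts[cell_sex == "female", kind == "chrY"] <- 0
  # organ specificity is exact: OSGs are silent outside their organ
  # (already 0 in expectation via mu; enforced exactly here)
  for (o in seq_len(nO)) {
    counts[organ_col == o, which(kind == "osg")[osg_organ != organs[o]]] <- 0
  }

  ## ---- planted violators --------------------------------------------------
  coding_bg <- bg_idx[biotype[bg_idx] %in% c("protein_coding", "miRNA")]
  # low-complexity: ~50 detected coding genes, nothing else
  for (i in v_lowcx) {
    counts[i, ] <- 0
    pick <- sample(coding_bg, 50)
    counts[i, pick] <- sample(1:5, 50, replace = TRUE)
  }
  # low-coding: > 200 detected "other"-biotype genes, 5 coding genes, no mito
  for (i in v_lowcod) {
    counts[i, ] <- 0
    pick <- sample(other_idx, 210)
    counts[i, pick] <- sample(1:3, 210, replace = TRUE)
    counts[i, sample(coding_bg, 5)] <- sample(2:4, 5, replace = TRUE)
  }
  # outliers: express nearly every admissible gene
  for (i in v_out) {
    ok <- kind %in% c("bg", "marker", "stable", "hkvar", "chrX")
    ok[kind == "osg"] <- osg_organ == cell_organ[i]
    ok[kind == "chrY"] <- cell_sex[i] == "male"
    counts[i, ok] <- 1L + rnbinom(sum(ok), mu = 2, size = 2)
  }

  ## ---- mitochondrial counts ----------------------------------------------
  mito_idx <- which(kind == "mito")
  mito_p <- c(0.40, 0.25, 0.15, 0.08, 0.05, 0.03, 0.02, 0.01, 0.005, 0.005)
  tot <- rowSums(counts)
  a <- 2.5
  frac <- clip(rbeta(ncells, a, a * (1 - cfg$mito_fraction_mean) /
                       cfg$mito_fraction_mean), 0, 0.12)
  frac[v_mito] <- runif(length(v_mito), 0.25, 0.35)
  frac[v_lowcod] <- 0                      # keep their coding count at 5
  frac[v_lowcx] <- 0
  mito_tot <- round(frac / (1 - frac) * tot)
  nz <- which(mito_tot > 0)
  if (length(nz)) {
    counts[nz, mito_idx] <- t(vapply(
      mito_tot[nz], function(n) rmultinom(1, n, mito_p)[, 1],
      numeric(length(mito_idx))))
  }

  ## ---- clip ordinary cells' detected counts into a 2-SD band -------------
  for (s in sample_ids) {
    rows <- which(cell_sample == s & !is_violator)
    if (length(rows) < 3L) next
    det <- rowSums(counts[rows, , drop = FALSE] > 0)
    m <- mean(det); sdev <- sd(det)
    lo <- ceiling(m - 2 * sdev); hi <- floor(m + 2 * sdev)
    for (k in seq_along(rows)) {
      i <- rows[k]
      if (det[k] > hi) {
        on_bg <- intersect(which(counts[i, ] > 0), bg_idx)
        counts[i, on_bg[sample.int(length(on_bg), det[k] - hi)]] <- 0
      } else if (det[k] < lo) {
        off_bg <- intersect(which(counts[i, ] == 0), bg_idx)
        counts[i, off_bg[sample.int(length(off_bg), lo - det[k])]] <- 1L
      }
    }
  }

  ## ---- assemble -----------------------------------------------------------
  mat <- cell_matrix(counts, sample_of_cell = cell_sample,
                     organ_of_cell = cell_organ, species = cfg$species,
                     cell_ids = cell_ids, gene_symbols = symbols)
  samples <- sample_metadata(sample_ids,
                             species = cfg$species,
                             organ = sample_organ,
                             declared_sex = "unknown")
  hkg <- c(stable[seq_len(n_hkg_stable)], hkvar)
  truth <- list(
    sex_of_sample = stats::setNames(sample_sex, sample_ids),
    stable_gene_symbols = stable,
    osg_map = split(osg, osg_organ)[organs],
    hkg_list = hkg,
    cluster_of_cell = stats::setNames(sprintf("T%d", cell_type), cell_ids),
    qc_violations = list(
      min_genes = cell_ids[v_lowcx],
      min_cells = cell_ids[v_small],
      coding = cell_ids[v_lowcod],
      mito = cell_ids[v_mito],
      outlier = cell_ids[v_out]
    )
  )
  list(matrix = mat, annotation = ann, samples = samples, truth = truth)
}

#' Confusion counts of a prediction against a planted truth
#'
#' One-vs-rest tally: an item is positive when its label equals `positive`.
#'
#' @param predicted named character vector of predicted labels.
#' @param truth named character vector of true labels (same names).
#' @param positive the label counted as positive.
#' @param universe allowed labels; defaults to the union of both vectors.
#'   Labels outside an explicitly supplied universe are an error.
#' @return A list with integer fields `TP`, `TN`, `FP`, `FN`;
#'   `TP+TN+FP+FN` equals the number of evaluated items.
#' @export
truth_confusion <- function(predicted, truth, positive,
                            universe = union(unique(predicted), unique(truth))) {
  if (is.null(names(predicted)) || is.null(names(truth))) {
    stop_format("predicted and truth must be named")
  }
  truth <- truth[names(predicted)]
  if (anyNA(truth)) stop_format("predicted names not covered by truth")
  bad <- setdiff(unique(c(predicted, truth)), universe)
  if (length(bad)) stop_format("unknown label(s): %s", paste(bad, collapse = ", "))
  if (!positive %in% universe) stop_format("positive label '%s' not in universe", positive)
  p <- predicted == positive; t <- truth == positive
  list(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}
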