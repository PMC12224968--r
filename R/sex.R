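#' Species presets for the expression-based sex classifier
#'
#' The decision constants for the human and mouse rule sets. Human:
#' `male_y = 0.001188` (Y-Ratio at or above which a sample is male
#' regardless of X-Ratio), `male_x = 0.000070`, `band_y = 0.000106`
#' (lower edge of the intermediate Y band), `female_x_min = 0.000001`.
#' Mouse: `male_y = 0.000065`, `male_x = 0.000008`,
#' `female_x = 0.000555`, `low_y = 0.000004` (below which any X signal
#' means female). All overridable for recalibration.
#'
#' @param species `"human"` or `"mouse"`.
#' @param ... named overrides of individual constants.
#' @return A list of class `sex_thresholds`.
#' @export
sex_thresholds <- function(species = c("human", "mouse"), ...) {
  species <- match.arg(species)
  th <- if (species == "human") {
    list(species = "human", male_y = 0.001188, male_x = 0.000070,
         band_y = 0.000106, female_x_min = 0.000001)
  } else {
    list(species = "mouse", male_y = 0.000065, male_x = 0.000008,
         female_x = 0.000555, low_y = 0.000004)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) stop_format("unknown threshold(s): %s", paste(bad, collapse = ", "))
  th[names(dots)] <- dots
  if (species == "human" && th$male_y <= th$band_y) {
    stop_format("male_y must exceed band_y")
  }
  if (species == "mouse" && th$male_y <= th$low_y) {
    stop_format("male_y must exceed low_y")
  }
  structure(th, class = "sex_thresholds")
}

#' Per-sample X-Ratio and Y-Ratio statistics
#'
#' Y-Ratio = FPKM of the Y marker gene (SRY/Sry) over the summed FPKM of all
#' chrY genes; X-Ratio = summed FPKM of chrX-unique genes (chrX genes with
#' no chrY homolog) over the summed FPKM of all chrX genes. A zero
#' denominator yields a ratio of 0, so corpora without any Y signal classify
#' female rather than erroring.
#'
#' @param pb a `pseudobulk` in FPKM units, one row per sample.
#' @param annotation a [gene_annotation()] marking chrX, chrY and
#'   chrX-unique genes.
#' @param sry_symbol the Y marker symbol; must be present in the annotation
#'   on chrY (`"SRY"` human, `"Sry"` mouse).
#' @return A data frame of class `sex_ratios` with columns `sample_id`,
#'   `SRY_expr`, `chrY_expr`, `chrX_uniq_expr`, `chrX_expr`, `y_ratio`,
#'   `x_ratio`.
#' @export
compute_sex_ratios <- function(pb, annotation, sry_symbol = "SRY") {
  stopifnot(inherits(pb, "pseudobulk"))
  if (pb$unit != "FPKM") stop_format("sex ratios expect FPKM pseudo-bulk input")
  chr <- annotation$chromosome[match(pb$gene_symbols, annotation$symbol)]
  uniqx <- annotation$is_chrX_unique[match(pb$gene_symbols, annotation$symbol)]
  if (!sry_symbol %in% annotation$symbol || !sry_symbol %in% pb$gene_symbols) {
    stop_format("Y marker gene '%s' absent from annotation or matrix", sry_symbol)
  }
  y_genes <- !is.na(chr) & chr == "chrY"
  x_genes <- !is.na(chr) & chr == "chrX"
  if (!any(y_genes)) stop_format("annotation contains no chrY genes")
  if (!any(x_genes)) stop_format("annotation contains no chrX genes")
  sry <- pb$values[, sry_symbol]
  ytot <- rowSums(pb$values[, y_genes, drop = FALSE])
  xuniq <- rowSums(pb$values[, x_genes & !is.na(uniqx) & uniqx, drop = FALSE])
  xtot <- rowSums(pb$values[, x_genes, drop = FALSE])
  out <- data.frame(
    sample_id = pb$group_ids,
    SRY_expr = sry, chrY_expr = ytot,
    chrX_uniq_expr = xuniq, chrX_expr = xtot,
    y_ratio = ifelse(ytot > 0, sry / ytot, 0),
    x_ratio = ifelse(xtot > 0, xuniq / xtot, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sex_ratios", "data.frame")
  out
}

# Single-pair classification; x, y are the X-Ratio and Y-Ratio.
.classify_one <- function(x, y, th) {
  if (is.na(x) || is.na(y)) return(NA_character_)
  if (th$species == "human") {
    if (y >= th$male_y || (x <= th$male_x && y > th$band_y)) return("male")
    if (x > th$male_x && y > th$band_y && y < th$male_y) return("mixed")
    if (x >= th$female_x_min && y <= th$band_y) return("female")
    return("unknown")
  }
  # mouse
  in_band <- y > th$low_y && y < th$male_y
  if (y >= th$male_y || (x <= th$male_x && in_band)) return("male")
  if ((x >= th$female_x && in_band) || (x > 0 && y <= th$low_y)) return("female")
  if (x > th$male_x && x < th$female_x && in_band) return("mixed")
  "unknown"
}

#' Classify sample sex from X/Y expression ratios
#'
#' Applies the species rule set with precedence male, then (human) mixed
#' before female / (mouse) female before mixed, then unknown, which makes
#' the rules a total function of (X-Ratio, Y-Ratio). Interval endpoints
#' belong to the >= / <= branches that cite them. `NaN` ratios give
#' `unknown` with a warning.
#'
#' @param ratios a `sex_ratios` data frame (or any data frame with
#'   `sample_id`, `x_ratio`, `y_ratio`).
#' @param thresholds a [sex_thresholds()] preset.
#' @return A data frame of class `sex_calls` with columns `sample_id`,
#'   `label`.
#' @export
classify_sex <- function(ratios, thresholds = sex_thresholds("human")) {
  stopifnot(inherits(thresholds, "sex_thresholds"))
  lab <- mapply(.classify_one, ratios$x_ratio, ratios$y_ratio,
                MoreArgs = list(th = thresholds))
  if (anyNA(lab)) {
    warning("NaN ratio(s) classified as unknown")
    lab[is.na(lab)] <- "unknown"
  }
  out <- data.frame(sample_id = ratios$sample_id, label = unname(lab),
                    stringsAsFactors = FALSE)
  class(out) <- c("sex_calls", "data.frame")
  out
}

#' Replace declared sex labels by classifier calls
#'
#' @param samples a [sample_metadata()] table.
#' @param calls a `sex_calls` data frame covering every sample.
#' @return A list with `samples` (metadata with `declared_sex` replaced) and
#'   `corrections`, a data frame with one row per sample
#'   (`sample_id`, `original`, `corrected`, `matched_declaration`) whose row
#'   count equals the number of samples (suitable for Sankey-style tallies).
#' @export
correct_sample_sex <- function(samples, calls) {
  stopifnot(inherits(samples, "sample_metadata"))
  idx <- match(samples$sample_id, calls$sample_id)
  if (anyNA(idx)) stop_format("calls do not cover all samples")
  corrected <- calls$label[idx]
  corrections <- data.frame(
    sample_id = samples$sample_id,
    original = samples$declared_sex,
    corrected = corrected,
    matched_declaration = samples$declared_sex == corrected,
    stringsAsFactors = FALSE)
  samples$declared_sex <- corrected
  list(samples = samples, corrections = corrections)
}

#' Calibrate the dominant male Y-Ratio threshold from labeled samples
#'
#' A deliberately simple grid search: candidate cut points are midpoints
#' between consecutive observed Y-Ratios; the candidate maximizing
#' male/female accuracy of the resulting classifier (all other constants
#' kept at the species preset) is returned as an updated
#' [sex_thresholds()]. Intended for gonadal (testis/ovary) samples whose
#' sex is unambiguous.
#'
#' @param ratios a `sex_ratios` data frame.
#' @param known_sex named vector (sample id -> "male"/"female").
#' @param species `"human"` or `"mouse"`.
#' @return A [sex_thresholds()] with `male_y` replaced by the fitted cut.
#' @export
calibrate_sex_thresholds <- function(ratios, known_sex,
                                     species = c("human", "mouse")) {
  species <- match.arg(species)
  truth <- known_sex[ratios$sample_id]
  if (anyNA(truth)) stop_format("known_sex must cover every sample")
  ys <- sort(unique(ratios$y_ratio))
  cands <- if (length(ys) > 1L) (ys[-1] + ys[-length(ys)]) / 2 else ys
  best <- sex_thresholds(species); best_acc <- -1
  for (cand in cands) {
    th <- tryCatch(sex_thresholds(species, male_y = cand),
                   error = function(e) NULL)
    if (is.null(th)) next
    acc <- mean(classify_sex(ratios, th)$label == truth)
    if (acc > best_acc) { best_acc <- acc; best <- th }
  }
  best
}
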