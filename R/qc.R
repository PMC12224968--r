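#' Quality-control configuration
#'
#' Thresholds for the staged QC cascade. Comparisons follow the rules'
#' wording literally: "fewer than" / "less than" / "exceeding" are strict,
#' so cells and samples are retained at exactly the threshold (>= for gene
#' and cell counts, <= for the mitochondrial fraction and the outlier
#' bound). A gene is "detected" when its count is strictly positive.
#'
#' @param min_genes_per_cell cells with fewer detected genes are removed.
#' @param min_cells_per_sample samples with fewer surviving cells are removed.
#' @param min_coding_genes_per_cell cells expressing fewer protein-coding or
#'   miRNA genes are removed.
#' @param max_mito_fraction cells whose mitochondrial count fraction exceeds
#'   this are removed.
#' @param outlier_sd_multiplier cells whose detected-gene count exceeds
#'   their sample mean by more than this many SDs are removed.
#' @param core_gene_list optional character vector; when given, the gene
#'   axis is restricted to it.
#' @param min_cells_per_annotated_type floor for the optional rare-cell-type
#'   stage (applied only when type labels are passed to [run_qc()]).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_genes_per_cell = 200,
                      min_cells_per_sample = 3,
                      min_coding_genes_per_cell = 7,
                      max_mito_fraction = 0.15,
                      outlier_sd_multiplier = 3,
                      core_gene_list = NULL,
                      min_cells_per_annotated_type = 20) {
  stopifnot(min_genes_per_cell > 0, min_cells_per_sample > 0,
            min_coding_genes_per_cell > 0,
            max_mito_fraction > 0, max_mito_fraction <= 1,
            outlier_sd_multiplier > 0, min_cells_per_annotated_type > 0)
  structure(as.list(environment()), class = "qc_config")
}

.drop_cells <- function(x, drop_idx) {
  keep <- setdiff(seq_len(nrow(x$counts)), drop_idx)
  list(matrix = subset_cells(x, cells = keep),
       removed = x$cell_ids[sort(drop_idx)])
}

#' QC stage: minimum detected genes per cell
#'
#' Removes cells with fewer than `min_genes` detected genes (count > 0).
#'
#' @param x a [cell_matrix()].
#' @param min_genes detection floor; a cell with exactly `min_genes`
#'   detected genes is retained.
#' @return A list with `matrix` (the filtered [cell_matrix()]) and `removed`
#'   (removed cell ids). All `filter_cells_*` stages share this shape.
#' @export
filter_cells_min_genes <- function(x, min_genes = 200) {
  det <- detected_genes_per_cell(x)
  .drop_cells(x, which(det < min_genes))
}

#' QC stage: minimum cells per sample
#'
#' Removes every cell of samples with fewer than `min_cells` cells. Run
#' after the cell-level stages so the census reflects survivors.
#'
#' @param x a [cell_matrix()].
#' @param min_cells retention floor; a sample with exactly `min_cells` cells
#'   is retained.
#' @return A list with `matrix`, `removed` (cell ids) and `removed_samples`.
#' @export
filter_samples_min_cells <- function(x, min_cells = 3) {
  census <- table(x$sample_of_cell)
  bad <- names(census)[census < min_cells]
  out <- .drop_cells(x, which(x$sample_of_cell %in% bad))
  if (nrow(out$matrix$counts) == 0L && nrow(x$counts) > 0L) {
    warning("all samples fell below the cell floor; empty matrix returned")
  }
  out$removed_samples <- bad
  out
}

#' QC stage: minimum expressed protein-coding/miRNA genes per cell
#'
#' @param x a [cell_matrix()].
#' @param annotation a [gene_annotation()]; genes absent from it count as
#'   biotype `other`.
#' @param min_coding floor on detected genes with biotype `protein_coding`
#'   or `miRNA` (pooled).
#' @return A list with `matrix` and `removed` (cell ids).
#' @export
filter_cells_coding <- function(x, annotation, min_coding = 7) {
  bt <- annotation$biotype[match(x$gene_symbols, annotation$symbol)]
  coding <- !is.na(bt) & bt %in% c("protein_coding", "miRNA")
  if (!any(coding)) {
    warning("no protein-coding/miRNA genes annotated; every cell fails this stage")
  }
  ncod <- Matrix::rowSums(x$counts[, coding, drop = FALSE] > 0)
  .drop_cells(x, which(ncod < min_coding))
}

#' QC stage: mitochondrial fraction
#'
#' Removes cells whose mitochondrial share of total counts strictly exceeds
#' `max_fraction` (a cell at exactly the threshold is retained), and cells
#' with zero total counts.
#'
#' @param x a [cell_matrix()].
#' @param annotation a [gene_annotation()] with `is_mitochondrial`.
#' @param max_fraction mitochondrial-fraction ceiling.
#' @return A list with `matrix` and `removed` (cell ids).
#' @export
filter_cells_mito <- function(x, annotation, max_fraction = 0.15) {
  mito <- annotation$is_mitochondrial[match(x$gene_symbols, annotation$symbol)]
  mito <- !is.na(mito) & mito
  tot <- Matrix::rowSums(x$counts)
  mtot <- if (any(mito)) Matrix::rowSums(x$counts[, mito, drop = FALSE]) else 0
  frac <- ifelse(tot > 0, mtot / tot, Inf)   # zero-total cells removed too
  .drop_cells(x, which(frac > max_fraction))
}

#' QC stage: detected-gene-count outliers within sample
#'
#' Removes cells whose detected-gene count exceeds mean + `sd_multiplier` *
#' SD of their own sample's cells (upper tail only). Samples with fewer
#' than 2 cells skip the stage.
#'
#' @param x a [cell_matrix()].
#' @param sd_multiplier the SD multiplier.
#' @return A list with `matrix` and `removed` (cell ids).
#' @export
filter_cells_outlier <- function(x, sd_multiplier = 3) {
  det <- detected_genes_per_cell(x)
  drop <- integer(0)
  for (s in unique(x$sample_of_cell)) {
    idx <- which(x$sample_of_cell == s)
    if (length(idx) < 2L) next
    d <- det[idx]
    cut <- mean(d) + sd_multiplier * sd(d)
    drop <- c(drop, idx[d > cut])
  }
  .drop_cells(x, drop)
}

#' QC stage: restrict to a core gene list
#'
#' @param x a [cell_matrix()].
#' @param core_list character vector of gene symbols to keep; matrix gene
#'   order is preserved.
#' @return A list with `matrix` and `removed_genes`.
#' @export
restrict_core_genes <- function(x, core_list) {
  if (length(core_list) == 0L) stop_format("core gene list is empty")
  keep <- x$gene_symbols %in% core_list
  if (!any(keep)) stop_format("core gene list shares no genes with the matrix")
  list(matrix = subset_cells(x, genes = which(keep)),
       removed_genes = x$gene_symbols[!keep])
}

#' QC stage: drop rare annotated cell types
#'
#' @param x a [cell_matrix()].
#' @param type_labels named character vector (cell id -> type); cells
#'   without a label are kept untouched, with a warning.
#' @param min_cells types with fewer cells are dropped; a type with exactly
#'   `min_cells` cells is retained.
#' @return A list with `matrix` and `removed` (cell ids).
#' @export
filter_rare_cell_types <- function(x, type_labels, min_cells = 20) {
  lab <- type_labels[x$cell_ids]
  if (anyNA(lab)) warning("some cells lack a type label; they are kept")
  census <- table(lab)
  bad <- names(census)[census < min_cells]
  .drop_cells(x, which(!is.na(lab) & lab %in% bad))
}

#' Run the full staged QC cascade
#'
#' Applies, in order: minimum detected genes per cell, minimum cells per
#' sample (on survivors), coding-gene floor, mitochondrial-fraction ceiling,
#' within-sample detected-count outlier trim, core-gene restriction (when a
#' core list is configured), and optionally the rare-cell-type floor (when
#' `type_labels` are given). Attrition is accounted stage by stage; the
#' cascade is idempotent.
#'
#' @param x a [cell_matrix()].
#' @param annotation a [gene_annotation()].
#' @param config a [qc_config()].
#' @param type_labels optional named vector enabling the rare-type stage.
#' @return A list with `matrix` (the clean [cell_matrix()]) and `report`, a
#'   `qc_report` whose `$stages` data frame has columns
#'   `stage, before, removed, after` plus `$samples_removed` and
#'   `$genes_removed`.
#' @export
run_qc <- function(x, annotation, config = qc_config(), type_labels = NULL) {
  stopifnot(inherits(x, "cell_matrix"), inherits(annotation, "gene_annotation"),
            inherits(config, "qc_config"))
  stages <- list()
  note <- function(name, before, removed) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, before = before, removed = removed,
      after = before - removed, stringsAsFactors = FALSE)
  }
  samples_removed <- character(0)

  st <- filter_cells_min_genes(x, config$min_genes_per_cell)
  note("min_genes", nrow(x$counts), length(st$removed)); x <- st$matrix

  st <- filter_samples_min_cells(x, config$min_cells_per_sample)
  note("min_cells", nrow(x$counts), length(st$removed)); x <- st$matrix
  samples_removed <- st$removed_samples

  st <- filter_cells_coding(x, annotation, config$min_coding_genes_per_cell)
  note("coding", nrow(x$counts), length(st$removed)); x <- st$matrix

  st <- filter_cells_mito(x, annotation, config$max_mito_fraction)
  note("mito", nrow(x$counts), length(st$removed)); x <- st$matrix

  st <- filter_cells_outlier(x, config$outlier_sd_multiplier)
  note("outlier", nrow(x$counts), length(st$removed)); x <- st$matrix

  genes_removed <- character(0)
  if (!is.null(config$core_gene_list)) {
    st <- restrict_core_genes(x, config$core_gene_list)
    genes_removed <- st$removed_genes
    note("core_genes", nrow(x$counts), 0L); x <- st$matrix
  }
  if (!is.null(type_labels)) {
    st <- filter_rare_cell_types(x, type_labels,
                                 config$min_cells_per_annotated_type)
    note("rare_types", nrow(x$counts) , length(st$removed)); x <- st$matrix
  }
  report <- structure(
    list(stages = do.call(rbind, stages),
         samples_removed = samples_removed,
         genes_removed = genes_removed),
    class = "qc_report")
  list(matrix = x, report = report)
}

#' Per-stage removed cell ids for the staged cascade
#'
#' Runs the same cascade as [run_qc()] but returns, per stage, exactly which
#' cell ids were removed (useful for auditing against a planted violation
#' roster).
#'
#' @inheritParams run_qc
#' @return Named list stage -> character vector of removed cell ids.
#' @export
qc_removals <- function(x, annotation, config = qc_config(), type_labels = NULL) {
  out <- list()
  st <- filter_cells_min_genes(x, config$min_genes_per_cell)
  out$min_genes <- st$removed; x <- st$matrix
  st <- filter_samples_min_cells(x, config$min_cells_per_sample)
  out$min_cells <- st$removed; x <- st$matrix
  st <- filter_cells_coding(x, annotation, config$min_coding_genes_per_cell)
  out$coding <- st$removed; x <- st$matrix
  st <- filter_cells_mito(x, annotation, config$max_mito_fraction)
  out$mito <- st$removed; x <- st$matrix
  st <- filter_cells_outlier(x, config$outlier_sd_multiplier)
  out$outlier <- st$removed; x <- st$matrix
  if (!is.null(type_labels)) {
    st <- filter_rare_cell_types(x, type_labels,
                                 config$min_cells_per_annotated_type)
    out$rare_types <- st$removed
  }
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(x$stages, row.names = FALSE)
  if (length(x$samples_removed)) {
    cat("samples removed:", paste(x$samples_removed, collapse = ", "), "\n")
  }
  if (length(x$genes_removed)) {
    cat("genes removed:", length(x$genes_removed), "\n")
  }
  invisible(x)
}

#' Write a QC report's stage table to TSV
#' @param report a `qc_report` from [run_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
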