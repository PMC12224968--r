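#' Cell-by-gene count matrix with sample and organ labels
#'
#' The pipeline's universal currency: a sparse cells x genes matrix of raw
#' integer counts plus per-cell sample and organ labels and a species tag.
#' Counts are stored as a `Matrix::dgCMatrix` with cells in rows and genes in
#' columns, so per-gene statistics (zero rates, non-zero medians) read the
#' sparse column slots directly and never densify.
#'
#' @param counts cells x genes matrix of non-negative integer counts (dense or
#'   sparse; coerced to `dgCMatrix`). Row names are taken as cell ids and
#'   column names as gene symbols when `cell_ids`/`gene_symbols` are missing.
#' @param sample_of_cell character vector, one sample id per cell.
#' @param organ_of_cell character vector, one organ per cell; defaults to
#'   `"unknown"` for every cell.
#' @param species species tag (free text, e.g. `"human"` or `"mouse"`).
#' @param cell_ids,gene_symbols unique identifiers; default to the dimnames of
#'   `counts`.
#'
#' @return An object of class `cell_matrix`: a list with elements `counts`,
#'   `cell_ids`, `gene_symbols`, `sample_of_cell`, `organ_of_cell`, `species`.
#' @examples
#' m <- cell_matrix(matrix(c(5, 0, 0, 0, 3, 0), nrow = 3,
#'                         dimnames = list(paste0("c", 1:3), c("A", "B"))),
#'                  sample_of_cell = c("s1", "s1", "s2"))
#' dim(m)
#' @export
cell_matrix <- function(counts, sample_of_cell,
                        organ_of_cell = NULL,
                        species = "unknown",
                        cell_ids = rownames(counts),
                        gene_symbols = colnames(counts)) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) {
    stop_format("cell ids are required (rownames of counts or `cell_ids`)")
  }
  if (is.null(gene_symbols)) {
    stop_format("gene symbols are required (colnames of counts or `gene_symbols`)")
  }
  cell_ids <- as.character(cell_ids)
  gene_symbols <- as.character(gene_symbols)
  if (length(cell_ids) != nrow(counts) || length(gene_symbols) != ncol(counts)) {
    stop_format("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(cell_ids)) stop_format("duplicate cell ids")
  if (anyDuplicated(gene_symbols)) stop_format("duplicate gene symbols")
  x <- counts@x
  if (length(x)) {
    if (anyNA(x)) stop_format("counts contain NA")
    if (any(x < 0)) stop_format("counts must be non-negative")
    if (any(x != trunc(x))) {
      stop_format("counts must be integers (first offender: %g)",
                  x[x != trunc(x)][1])
    }
  }
  sample_of_cell <- as.character(sample_of_cell)
  if (length(sample_of_cell) == 1L) {
    sample_of_cell <- rep(sample_of_cell, nrow(counts))
  }
  if (length(sample_of_cell) != nrow(counts)) {
    stop_format("sample_of_cell must name a sample for every cell")
  }
  if (anyNA(sample_of_cell) || any(!nzchar(sample_of_cell))) {
    stop_format("every cell needs a non-empty sample label")
  }
  if (is.null(organ_of_cell)) organ_of_cell <- rep("unknown", nrow(counts))
  organ_of_cell <- as.character(organ_of_cell)
  if (length(organ_of_cell) == 1L) organ_of_cell <- rep(organ_of_cell, nrow(counts))
  if (length(organ_of_cell) != nrow(counts)) {
    stop_format("organ_of_cell must label every cell")
  }
  organ_of_cell[is.na(organ_of_cell) | !nzchar(organ_of_cell)] <- "unknown"
  dimnames(counts) <- list(cell_ids, gene_symbols)
  structure(
    list(counts = counts, cell_ids = cell_ids, gene_symbols = gene_symbols,
         sample_of_cell = sample_of_cell, organ_of_cell = organ_of_cell,
         species = as.character(species)[1]),
    class = "cell_matrix"
  )
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts), x$species))
  cat(sprintf("  samples: %d | organs: %s | nnz: %d\n",
              length(unique(x$sample_of_cell)),
              paste(unique(x$organ_of_cell), collapse = ", "),
              length(x$counts@x)))
  invisible(x)
}

#' Subset a cell_matrix by cells and/or genes
#'
#' @param x a [cell_matrix()].
#' @param cells logical/integer/character index over cells (default: all).
#' @param genes logical/integer/character index over genes (default: all).
#' @return A `cell_matrix` restricted to the selection; label vectors follow.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  ci <- if (is.null(cells)) seq_len(nrow(x$counts)) else cells
  if (is.character(ci)) ci <- match(ci, x$cell_ids)
  if (is.logical(ci)) ci <- which(ci)
  gi <- if (is.null(genes)) seq_len(ncol(x$counts)) else genes
  if (is.character(gi)) gi <- match(gi, x$gene_symbols)
  if (is.logical(gi)) gi <- which(gi)
  if (anyNA(ci)) stop_format("unknown cell id in subset")
  if (anyNA(gi)) stop_format("unknown gene symbol in subset")
  cell_matrix(x$counts[ci, gi, drop = FALSE],
              sample_of_cell = x$sample_of_cell[ci],
              organ_of_cell = x$organ_of_cell[ci],
              species = x$species,
              cell_ids = x$cell_ids[ci],
              gene_symbols = x$gene_symbols[gi])
}

#' Number of detected genes per cell
#'
#' A gene is "detected" in a cell when its count is strictly positive.
#'
#' @param x a [cell_matrix()].
#' @return Integer vector, one entry per cell, named by cell id.
#' @export
detected_genes_per_cell <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  n <- Matrix::rowSums(x$counts > 0)
  stats::setNames(as.integer(n), x$cell_ids)
}
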