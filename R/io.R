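#' Read a 10x-style Matrix Market triplet into a cell_matrix
#'
#' Reads `matrix.mtx` plus `barcodes.tsv` and `features.tsv` (one entry per
#' line; features may carry extra tab-separated columns, the first is taken
#' as the symbol). Orientation (genes x cells, the 10x convention, versus
#' cells x genes) is auto-detected from the barcode and feature counts.
#'
#' Cells are mapped to samples either through an explicit two-column
#' `barcode_map` file (`barcode<TAB>sample_id`, no header) or, failing that,
#' by the barcode suffix convention `<barcode>-<sample_id>`. The map file
#' wins when both are available. When neither applies, every cell is assigned
#' to sample `"sample1"`.
#'
#' @param matrix_path path to the MTX file.
#' @param barcodes_path path to the barcodes file (one barcode per line).
#' @param features_path path to the features file.
#' @param sample_table optional [sample_metadata()]; joined by sample id to
#'   fill organ labels and the species tag.
#' @param barcode_map optional path to a two-column barcode-to-sample map.
#' @return A [cell_matrix()].
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path,
                     sample_table = NULL, barcode_map = NULL) {
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop_format("file not found: %s", p)
  }
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path, warn = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  feats <- readLines(features_path, warn = FALSE)
  feats <- feats[nzchar(feats)]
  symbols <- vapply(strsplit(feats, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (anyDuplicated(barcodes)) stop_format("duplicate barcodes in %s", barcodes_path)
  if (anyDuplicated(symbols)) stop_format("duplicate gene symbols in %s", features_path)
  nb <- length(barcodes); ng <- length(symbols)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)                      # 10x convention: genes x cells
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    stop_format(
      "MTX dimensions %d x %d match neither %d barcodes x %d features nor its transpose",
      nrow(m), ncol(m), nb, ng)
  }
  samples <- .barcode_samples(barcodes, barcode_map)
  organ <- NULL; species <- "unknown"
  if (!is.null(sample_table)) {
    stopifnot(inherits(sample_table, "sample_metadata"))
    idx <- match(samples, sample_table$sample_id)
    organ <- ifelse(is.na(idx), "unknown", sample_table$organ[idx])
    sp <- unique(sample_table$species[idx[!is.na(idx)]])
    if (length(sp) == 1L) species <- sp
  }
  cell_matrix(m, sample_of_cell = samples, organ_of_cell = organ,
              species = species, cell_ids = barcodes, gene_symbols = symbols)
}

.barcode_samples <- function(barcodes, barcode_map = NULL) {
  if (!is.null(barcode_map)) {
    map <- utils::read.delim(barcode_map, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(map) < 2L) stop_format("barcode map needs two columns")
    idx <- match(barcodes, map[[1]])
    if (anyNA(idx)) {
      stop_format("%d barcode(s) absent from the barcode map", sum(is.na(idx)))
    }
    return(as.character(map[[2]][idx]))
  }
  has_suffix <- grepl("-", barcodes, fixed = TRUE)
  if (all(has_suffix)) {
    sub("^.*-", "", barcodes)
  } else {
    rep("sample1", length(barcodes))
  }
}

#' Write / read a corpus directory
#'
#' The package's on-disk corpus format is a plain-text directory: a Matrix
#' Market triplet in the 10x orientation (`matrix.mtx`, genes x cells) with
#' `barcodes.tsv` and `features.tsv`, a `cells.tsv` table carrying the
#' per-cell sample and organ labels, and a `corpus.json` with the species
#' tag. Text files diff cleanly and the write/read round trip is exact on
#' counts, ids and labels.
#'
#' @param x a [cell_matrix()].
#' @param dir directory to create (overwritten if it exists).
#' @return `write_corpus` returns `dir` invisibly; `read_corpus` returns the
#'   reconstructed [cell_matrix()].
#' @export
write_corpus <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(x$gene_symbols, file.path(dir, "features.tsv"))
  utils::write.table(
    data.frame(cell_id = x$cell_ids, sample = x$sample_of_cell,
               organ = x$organ_of_cell, stringsAsFactors = FALSE),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(list(species = x$species), auto_unbox = TRUE),
             file.path(dir, "corpus.json"))
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "corpus.json"))
  m <- read_mtx(file.path(dir, "matrix.mtx"),
                file.path(dir, "barcodes.tsv"),
                file.path(dir, "features.tsv"))
  idx <- match(m$cell_ids, cells$cell_id)
  if (anyNA(idx)) stop_format("cells.tsv does not cover all barcodes")
  cell_matrix(m$counts, sample_of_cell = cells$sample[idx],
              organ_of_cell = cells$organ[idx], species = meta$species,
              cell_ids = m$cell_ids, gene_symbols = m$gene_symbols)
}
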