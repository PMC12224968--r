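#' Corpus-level non-zero gene medians
#'
#' For each gene, the median of its strictly positive counts over the
#' corpus; genes never expressed are absent from the table. Zeros are
#' excluded because including them would collapse most medians to 0 and
#' break median-normalized division.
#'
#' @param x a [cell_matrix()] (typically post-QC).
#' @return Named numeric vector (symbol -> median > 0) of class
#'   `gene_medians`, covering exactly the genes with at least one non-zero
#'   count.
#' @export
compute_gene_medians <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  counts <- x$counts
  if (length(counts@x) == 0L) stop_format("corpus has no non-zero counts")
  gene_of_val <- rep(seq_len(ncol(counts)), .col_nnz(counts))
  med <- vapply(split(counts@x, gene_of_val), stats::median, numeric(1))
  structure(stats::setNames(med, x$gene_symbols[as.integer(names(med))]),
            class = "gene_medians")
}

#' Rank-encode one cell
#'
#' Divides each expressed gene's count by its corpus median and orders genes
#' by the normalized value, descending; ties are broken by symbol,
#' ascending, so the encoding is deterministic. Zero-count genes are
#' excluded. Scaling all counts of a cell by a constant leaves the gene
#' order unchanged.
#'
#' @param cell_counts named numeric vector (symbol -> raw count) for one
#'   cell.
#' @param medians a `gene_medians` table from [compute_gene_medians()].
#' @param truncate optional maximum sequence length (default: none).
#' @return A list with `genes` (ordered symbols) and `values` (their
#'   median-normalized expression, same order).
#' @export
rank_encode <- function(cell_counts, medians, truncate = Inf) {
  expressed <- cell_counts[cell_counts > 0]
  expressed <- expressed[names(expressed) %in% names(medians)]
  norm <- expressed / unclass(medians)[names(expressed)]
  ord <- order(-norm, names(norm))
  if (is.finite(truncate)) ord <- utils::head(ord, truncate)
  list(genes = names(norm)[ord], values = unname(norm[ord]))
}

#' Export a corpus in model-ready shapes
#'
#' `format = "ranked_jsonl"` writes one JSON line per cell
#' (`{"cell_id": ..., "genes": [...], "values": [...]}`, rank-encoded) plus
#' a `vocab.tsv` (symbol, integer id, cell frequency) covering exactly the
#' expressed genes, ids assigned by descending frequency then symbol.
#' `format = "matrix_dir"` writes the corpus directory of [write_corpus()]
#' plus a `gene_medians.tsv` sidecar. Both exports are byte-deterministic
#' given their input.
#'
#' @param x a [cell_matrix()].
#' @param medians a `gene_medians` table.
#' @param format `"ranked_jsonl"` or `"matrix_dir"`.
#' @param path output directory.
#' @param truncate optional maximum ranked-sequence length.
#' @return `path`, invisibly.
#' @export
export_corpus <- function(x, medians, format = c("ranked_jsonl", "matrix_dir"),
                          path, truncate = Inf) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "matrix_dir") {
    write_corpus(x, path)
    utils::write.table(
      data.frame(symbol = names(medians), median = unclass(medians),
                 stringsAsFactors = FALSE),
      file.path(path, "gene_medians.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  freq <- stats::setNames(.col_nnz(x$counts), x$gene_symbols)
  freq <- freq[freq > 0]
  vocab <- data.frame(symbol = names(freq), frequency = as.integer(freq),
                      stringsAsFactors = FALSE)
  vocab <- vocab[order(-vocab$frequency, vocab$symbol), ]
  vocab$id <- seq_len(nrow(vocab)) - 1L
  utils::write.table(vocab[, c("symbol", "id", "frequency")],
                     file.path(path, "vocab.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(path, "cells.jsonl"), open = "wb")
  on.exit(close(con))
  dense <- as.matrix(x$counts)
  for (i in seq_len(nrow(dense))) {
    enc <- rank_encode(dense[i, ], medians, truncate = truncate)
    line <- jsonlite::toJSON(
      list(cell_id = x$cell_ids[i], genes = enc$genes,
           values = round(enc$values, 6)),
      auto_unbox = TRUE, digits = NA)
    writeLines(line, con)
  }
  invisible(path)
}
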