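#' Per-gene zero-rate over cells
#'
#' Fraction of cells in which the gene's count is exactly zero; read from
#' the sparse column slots, never densifying.
#'
#' @param x a [cell_matrix()] (typically post-QC).
#' @return Named numeric vector in \[0, 1\], one entry per gene.
#' @export
gene_zero_rate <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  n <- nrow(x$counts)
  if (n == 0L) stop_format("zero-rate undefined on an empty matrix")
  stats::setNames(1 - .col_nnz(x$counts) / n, x$gene_symbols)
}

#' Combine zero-rate and CV rankings into a gene stability table
#'
#' Genes are ranked ascending by zero-rate and, independently, ascending by
#' CV (`Inf` CVs rank last). The combined score is the sum of the two
#' ranks; the final stability order is ascending in that score. All ties are
#' broken by gene symbol, lexicographically, so the ranking is a
#' deterministic total order that is invariant to input gene order.
#'
#' @param zero_rates named numeric vector from [gene_zero_rate()].
#' @param cvs named numeric vector from [gene_cv()] over the same genes.
#' @return A data frame of class `gene_stability`, ordered by
#'   `combined_rank`, with columns `symbol`, `zero_rate`, `cv`, `zero_rank`,
#'   `cv_rank`, `combined_rank`.
#' @export
rank_stability <- function(zero_rates, cvs) {
  if (!setequal(names(zero_rates), names(cvs))) {
    stop_format("zero_rates and cvs must cover the same genes")
  }
  sym <- sort(names(zero_rates))              # canonical order for tie-breaks
  z <- zero_rates[sym]; cv <- cvs[sym]
  zero_rank <- order(order(z, sym))
  cv_rank <- order(order(cv, sym))            # Inf sorts last
  score <- zero_rank + cv_rank
  combined_rank <- order(order(score, sym))
  out <- data.frame(symbol = sym, zero_rate = unname(z), cv = unname(cv),
                    zero_rank = zero_rank, cv_rank = cv_rank,
                    combined_rank = combined_rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$combined_rank), ]
  rownames(out) <- NULL
  class(out) <- c("gene_stability", "data.frame")
  out
}

#' Select stable-expression genes (SEGs)
#'
#' Takes the top-ranked genes from a stability table, as many as there are
#' housekeeping reference genes present in the gene universe (reference
#' genes absent from the matrix are ignored, with a warning).
#'
#' @param stability a `gene_stability` table from [rank_stability()].
#' @param hkg_list character vector of housekeeping reference symbols.
#' @return Character vector of SEG symbols in stability order.
#' @export
select_segs <- function(stability, hkg_list) {
  if (length(hkg_list) == 0L) stop_format("housekeeping reference list is empty")
  present <- intersect(unique(hkg_list), stability$symbol)
  if (length(present) < length(unique(hkg_list))) {
    warning(sprintf("%d reference gene(s) absent from the matrix are ignored",
                    length(unique(hkg_list)) - length(present)))
  }
  if (length(present) == 0L) {
    stop_format("no housekeeping reference gene occurs in the gene universe")
  }
  stability$symbol[seq_len(length(present))]
}

#' Overlap of a SEG set with the housekeeping reference
#'
#' @param seg_list,hkg_list non-empty character vectors.
#' @return `|intersection| / |hkg_list|`, in \[0, 1\].
#' @export
hkg_overlap <- function(seg_list, hkg_list) {
  if (!length(seg_list) || !length(hkg_list)) {
    stop_format("both gene lists must be non-empty")
  }
  length(intersect(unique(seg_list), unique(hkg_list))) / length(unique(hkg_list))
}
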