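#' Per-organ gene zero-rates
#'
#' Computes, for each gene and organ, the fraction of that organ's cells
#' with a zero count. Organs with fewer than `min_cells_per_organ` cells are
#' excluded (warning); if none remains, an error is raised.
#'
#' @param x a [cell_matrix()] with organ labels.
#' @param min_cells_per_organ floor guarding against degenerate rates from
#'   tiny organs.
#' @return A list of class `organ_zero_rates`: `rates` (genes x organs
#'   matrix in \[0, 1\]) and `cells_per_organ` (named counts).
#' @export
organ_zero_rates <- function(x, min_cells_per_organ = 50) {
  stopifnot(inherits(x, "cell_matrix"))
  census <- table(x$organ_of_cell)
  small <- names(census)[census < min_cells_per_organ]
  if (length(small)) {
    warning(sprintf("organ(s) below the %d-cell floor excluded: %s",
                    min_cells_per_organ, paste(small, collapse = ", ")))
  }
  organs <- sort(setdiff(names(census), small))
  if (!length(organs)) stop_format("no organ reaches the %d-cell floor",
                                   min_cells_per_organ)
  rates <- vapply(organs, function(o) {
    idx <- which(x$organ_of_cell == o)
    1 - .col_nnz(x$counts[idx, , drop = FALSE]) / length(idx)
  }, numeric(ncol(x$counts)))
  dimnames(rates) <- list(x$gene_symbols, organs)
  structure(list(rates = rates,
                 cells_per_organ = as.integer(census[organs])),
            class = "organ_zero_rates")
}

#' Call organ-specific genes (OSGs)
#'
#' A gene counts as expressed in an organ when its zero-rate there is at
#' most `expressed_max_zero_rate` (a rate of exactly the threshold counts as
#' expressed). OSGs are genes expressed in at least one and at most
#' `max_organs` organs; each such gene is assigned to every organ in which
#' it is expressed.
#'
#' @param ozr an `organ_zero_rates` object.
#' @param expressed_max_zero_rate expression criterion on the zero-rate.
#' @param max_organs specificity ceiling.
#' @return A data frame of class `osg_calls` with one row per (gene,
#'   assigned organ): columns `symbol`, `organ`, `zero_rate`,
#'   `n_organs_expressed`.
#' @export
call_osgs <- function(ozr, expressed_max_zero_rate = 0.90, max_organs = 2) {
  stopifnot(inherits(ozr, "organ_zero_rates"))
  expressed <- ozr$rates <= expressed_max_zero_rate
  n_expr <- rowSums(expressed)
  is_osg <- n_expr >= 1 & n_expr <= max_organs
  rows <- which(expressed & is_osg, arr.ind = TRUE)
  out <- data.frame(
    symbol = rownames(ozr$rates)[rows[, 1]],
    organ = colnames(ozr$rates)[rows[, 2]],
    zero_rate = ozr$rates[rows],
    n_organs_expressed = n_expr[rows[, 1]],
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$symbol, out$organ), ]
  rownames(out) <- NULL
  class(out) <- c("osg_calls", "data.frame")
  out
}

#' OSG calls as an organ -> genes map
#' @param calls an `osg_calls` data frame.
#' @return Named list, organ -> sorted character vector of OSG symbols.
#' @export
osg_map <- function(calls) {
  lapply(split(calls$symbol, calls$organ), function(s) sort(unique(s)))
}
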