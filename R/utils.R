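#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix Matrix t readMM writeMM sparseMatrix colSums rowSums
#' @importFrom methods as is new
#' @importFrom stats kmeans median rnbinom rbinom rbeta rmultinom rnorm runif
#'   dist sd setNames var
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_format <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Number of cells with a zero count for each gene, from the sparse slots.
.col_nnz <- function(counts) {
  stopifnot(is(counts, "CsparseMatrix"))
  diff(counts@p)
}
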