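#' Aggregate single cells into pseudo-bulk profiles
#'
#' Sums raw counts over all cells of each group; total mass is conserved
#' exactly.
#'
#' @param x a [cell_matrix()].
#' @param group_by `"sample"`, `"organ"`, or a named character vector
#'   (cell id -> group, e.g. cluster labels).
#' @return A list of class `pseudobulk` with `values` (groups x genes dense
#'   matrix), `group_ids`, `gene_symbols` and `unit` (`"counts"` here).
#' @export
aggregate_pseudobulk <- function(x, group_by = "sample") {
  stopifnot(inherits(x, "cell_matrix"))
  groups <- if (is.character(group_by) && length(group_by) == 1L) {
    switch(group_by,
           sample = x$sample_of_cell,
           organ = x$organ_of_cell,
           stop_format("group_by must be 'sample', 'organ' or a label vector"))
  } else {
    lab <- group_by[x$cell_ids]
    if (anyNA(lab)) stop_format("grouping labels missing for some cells")
    as.character(lab)
  }
  ids <- sort(unique(groups))
  ind <- Matrix::sparseMatrix(i = match(groups, ids),
                              j = seq_along(groups),
                              x = 1, dims = c(length(ids), length(groups)))
  vals <- as.matrix(ind %*% x$counts)
  dimnames(vals) <- list(ids, x$gene_symbols)
  structure(list(values = vals, group_ids = ids,
                 gene_symbols = x$gene_symbols, unit = "counts"),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d groups x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Convert pseudo-bulk counts to FPKM
#'
#' FPKM(g, j) = counts(g, j) * 1e9 / (length_j * total_g), with length_j the
#' gene's exonic length in bp and total_g the group's total counts. Groups
#' with zero total counts get an all-zero row, with a warning.
#'
#' @param pb a `pseudobulk` in counts.
#' @param annotation a [gene_annotation()] supplying `exonic_length_bp`.
#' @return A `pseudobulk` with `unit = "FPKM"`.
#' @export
counts_to_fpkm <- function(pb, annotation) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (pb$unit != "counts") stop_format("input must be in counts, got %s", pb$unit)
  len <- annotation$exonic_length_bp[match(pb$gene_symbols, annotation$symbol)]
  if (anyNA(len)) {
    stop_format("missing exonic length for gene(s): %s",
                paste(utils::head(pb$gene_symbols[is.na(len)], 5), collapse = ", "))
  }
  tot <- rowSums(pb$values)
  if (any(tot == 0)) {
    warning("group(s) with zero total counts get all-zero FPKM rows")
  }
  scale <- ifelse(tot > 0, 1e9 / tot, 0)
  vals <- sweep(pb$values * scale, 2L, len, `/`)
  structure(list(values = vals, group_ids = pb$group_ids,
                 gene_symbols = pb$gene_symbols, unit = "FPKM"),
            class = "pseudobulk")
}

#' Per-gene coefficient of variation across pseudo-bulk groups
#'
#' CV_j = SD over groups / mean over groups, with the sample SD (n - 1
#' denominator). Genes with zero mean get `Inf` (least stable).
#'
#' @param pb a `pseudobulk` (any unit; FPKM in the stability workflow).
#' @return Named numeric vector of CVs, one per gene.
#' @export
gene_cv <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (nrow(pb$values) < 2L) stop_format("CV needs at least 2 groups")
  m <- colMeans(pb$values)
  s <- apply(pb$values, 2L, stats::sd)
  cv <- ifelse(m > 0, s / m, Inf)
  stats::setNames(cv, pb$gene_symbols)
}

#' Pool cells within clusters into pseudo-cells
#'
#' Within each cluster, cells are randomly partitioned (seeded) into pools
#' of `pool_size` and summed. A remainder pool is kept iff it holds at least
#' `pool_size / 2` cells. Each pseudo-cell inherits the cluster id as its
#' sample label and the cluster's majority organ.
#'
#' @param x a [cell_matrix()].
#' @param cluster_labels named character vector, cell id -> cluster.
#' @param pool_size cells per pool.
#' @param seed RNG seed for the partition.
#' @return A [cell_matrix()] of pseudo-cells.
#' @export
pool_pseudocells <- function(x, cluster_labels, pool_size = 100, seed = 1) {
  stopifnot(inherits(x, "cell_matrix"))
  lab <- cluster_labels[x$cell_ids]
  if (anyNA(lab)) stop_format("cluster labels missing for some cells")
  with_seed(seed, {
    rows <- list(); ids <- character(0); organs <- character(0)
    for (cl in sort(unique(lab))) {
      idx <- sample(which(lab == cl))
      n_full <- length(idx) %/% pool_size
      rem <- length(idx) %% pool_size
      n_pools <- n_full + (rem >= pool_size / 2)
      maj_organ <- names(which.max(table(x$organ_of_cell[lab == cl])))
      for (p in seq_len(n_pools)) {
        take <- idx[(pool_size * (p - 1) + 1):min(pool_size * p, length(idx))]
        rows[[length(rows) + 1L]] <-
          Matrix::colSums(x$counts[take, , drop = FALSE])
        ids <- c(ids, sprintf("pseudo-%s-%03d", cl, p))
        organs <- c(organs, maj_organ)
      }
    }
    if (!length(rows)) stop_format("no pools produced; clusters too small")
    m <- do.call(rbind, rows)
    cell_matrix(m, sample_of_cell = sub("-[0-9]+$", "", ids),
                organ_of_cell = organs, species = x$species,
                cell_ids = ids, gene_symbols = x$gene_symbols)
  })
}

#' Write a pseudo-bulk matrix to TSV (groups as rows, genes as columns)
#' @param pb a `pseudobulk`.
#' @param path output path.
#' @export
write_pseudobulk <- function(pb, path) {
  df <- data.frame(group = pb$group_ids, pb$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
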