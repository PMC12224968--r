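#' Seeded k-means clustering
#'
#' Lloyd's algorithm with the best of `n_init` random starts (by total
#' within-cluster sum of squares), deterministic given `seed`.
#'
#' @param points numeric matrix, observations in rows.
#' @param k number of clusters; must not exceed the number of points.
#' @param seed RNG seed.
#' @param n_init random restarts.
#' @param max_iter Lloyd iterations per start.
#' @return Integer cluster labels, one per point.
#' @export
kmeans_cluster <- function(points, k, seed = 1, n_init = 10, max_iter = 300) {
  points <- as.matrix(points)
  if (k > nrow(points)) {
    stop_format("k = %d exceeds the number of points (%d)", k, nrow(points))
  }
  with_seed(seed, {
    fit <- suppressWarnings(
      stats::kmeans(points, centers = k, nstart = n_init,
                    iter.max = max_iter, algorithm = "Lloyd"))
    as.integer(fit$cluster)
  })
}

#' Calinski-Harabasz index
#'
#' CH = \[B / (k - 1)\] / \[W / (n - k)\] with B the between-cluster and W
#' the within-cluster sum of squared Euclidean distances to the respective
#' centroids. W = 0 (e.g. singleton clusters only) yields `Inf`.
#'
#' @param points numeric matrix, observations in rows.
#' @param labels cluster assignment, at least 2 non-empty clusters.
#' @return A non-negative number (possibly `Inf`).
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  cl <- unique(labels)
  k <- length(cl); n <- nrow(points)
  if (k < 2L) stop_format("need at least 2 clusters")
  mu <- colMeans(points)
  B <- 0; W <- 0
  for (c in cl) {
    xs <- points[labels == c, , drop = FALSE]
    muc <- colMeans(xs)
    B <- B + nrow(xs) * sum((muc - mu)^2)
    W <- W + sum(sweep(xs, 2L, muc)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Mean silhouette score
#'
#' Mean over points of (b - a) / max(a, b), where a is the mean distance to
#' the point's own cluster and b the smallest mean distance to another
#' cluster; points in singleton clusters score 0.
#'
#' @param points numeric matrix, observations in rows.
#' @param labels cluster assignment, at least 2 clusters.
#' @return A number in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop_format("need at least 2 clusters")
  sil <- cluster::silhouette(labels, stats::dist(points))
  mean(sil[, "sil_width"])
}

#' Top variable genes by log1p count variance
#'
#' Ranks genes by the variance of `log1p(count)` over cells (computed from
#' the sparse slots) and returns the top `n` symbols.
#'
#' @param x a [cell_matrix()].
#' @param n number of genes to return.
#' @return Character vector of `n` gene symbols, most variable first.
#' @export
top_variable_genes <- function(x, n = 100) {
  stopifnot(inherits(x, "cell_matrix"))
  nc <- nrow(x$counts)
  v <- x$counts; v@x <- log1p(v@x)
  s1 <- Matrix::colSums(v); v@x <- v@x^2
  s2 <- Matrix::colSums(v)
  vr <- s2 / nc - (s1 / nc)^2
  x$gene_symbols[order(-vr, x$gene_symbols)][seq_len(min(n, length(vr)))]
}

#' Clustering-based evaluation of gene sets
#'
#' For each of `n_repeats` seeded repeats: draw a random subsample of cells;
#' then, for every gene set, restrict the matrix to the set, library-size
#' normalize (counts scaled to 10,000 per cell, totals taken over all
#' genes), log1p-transform, run seeded k-means, and score the resulting
#' partition with the Calinski-Harabasz index and the silhouette score.
#'
#' @param x a [cell_matrix()].
#' @param gene_sets named list of character vectors; each must intersect the
#'   matrix genes.
#' @param k clusters for k-means.
#' @param n_repeats subsampling repeats.
#' @param subsample_size cells per repeat (must not exceed the cell count).
#' @param seed master seed; repeat r uses `seed + r`.
#' @return A data frame with columns `gene_set`, `rep`, `ch_index`,
#'   `silhouette`, one row per (set, repeat).
#' @export
evaluate_gene_sets <- function(x, gene_sets, k = 4, n_repeats = 20,
                               subsample_size = 500, seed = 1) {
  stopifnot(inherits(x, "cell_matrix"), length(gene_sets) > 0,
            !is.null(names(gene_sets)))
  n <- nrow(x$counts)
  if (subsample_size > n) {
    stop_format("subsample_size %d exceeds cell count %d", subsample_size, n)
  }
  sets <- lapply(gene_sets, function(g) {
    idx <- which(x$gene_symbols %in% g)
    if (!length(idx)) stop_format("a gene set shares no genes with the matrix")
    idx
  })
  res <- list()
  for (r in seq_len(n_repeats)) {
    cells <- with_seed(seed + r, sample.int(n, subsample_size))
    sub <- x$counts[cells, , drop = FALSE]
    tot <- Matrix::rowSums(sub)
    tot[tot == 0] <- 1
    norm <- log1p(as.matrix(sub) * (1e4 / tot))
    for (s in names(sets)) {
      pts <- norm[, sets[[s]], drop = FALSE]
      lab <- kmeans_cluster(pts, k, seed = seed + r)
      res[[length(res) + 1L]] <- data.frame(
        gene_set = s, rep = r,
        ch_index = calinski_harabasz(pts, lab),
        silhouette = silhouette_score(pts, lab),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Accuracy, recall and precision from confusion counts
#'
#' A = (TP + TN) / (TP + TN + FP + FN); R = TP / (TP + FN);
#' P = TP / (TP + FP). A metric whose denominator is zero is reported as
#' `NA` (absent), never as `NaN`.
#'
#' @param TP,TN,FP,FN non-negative integer counts, not all zero.
#' @return A list of class `classification_metrics` with fields `TP`, `TN`,
#'   `FP`, `FN`, `accuracy`, `recall`, `precision`.
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop_format("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_format("confusion counts are all zero")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = (TP + TN) / sum(counts),
                 recall = div(TP, TP + FN),
                 precision = div(TP, TP + FP)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.4f", v)
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | accuracy=%s recall=%s precision=%s\n",
              x$TP, x$TN, x$FP, x$FN, fmt(x$accuracy), fmt(x$recall),
              fmt(x$precision)))
  invisible(x)
}
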