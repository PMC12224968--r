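# Independent direct-formula oracles, written as plain loops.
brute_ch <- function(points, labels) {
  points <- as.matrix(points)
  cl <- unique(labels)
  n <- nrow(points); k <- length(cl)
  mu <- colMeans(points)
  B <- 0; W <- 0
  for (c in cl) {
    idx <- which(labels == c)
    muc <- colMeans(points[idx, , drop = FALSE])
    B <- B + length(idx) * sum((muc - mu)^2)
    for (i in idx) W <- W + sum((points[i, ] - muc)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

brute_sil <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (c in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == c]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

test_that("k-means separates well-separated blobs and is seed-deterministic", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- kmeans_cluster(pts, 2, seed = 1)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])

  set.seed(2); pts2 <- matrix(rnorm(40), 20, 2)
  expect_identical(kmeans_cluster(pts2, 3, seed = 5),
                   kmeans_cluster(pts2, 3, seed = 5))
  # k = n: every point its own cluster
  labn <- kmeans_cluster(pts2, 20, seed = 1)
  expect_equal(length(unique(labn)), 20L)
  expect_error(kmeans_cluster(pts2, 21, seed = 1), "exceeds")
})

test_that("Calinski-Harabasz matches the hand-computed 1-D example", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinski_harabasz(pts, c(1, 1, 2, 2)), 200)
  # single point per cluster: W = 0 sentinel
  expect_equal(calinski_harabasz(matrix(c(0, 5), ncol = 1), c(1, 2)), Inf)
  expect_error(calinski_harabasz(pts, rep(1, 4)), "2 clusters")
})

test_that("silhouette matches the hand-computed 1-D example and degenerate cases", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  # per-point widths: (10.5-1)/10.5, (9.5-1)/9.5, and symmetric
  expect_equal(silhouette_score(pts, c(1, 1, 2, 2)),
               (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)
  # two coincident clusters score at or below zero
  co <- matrix(rep(c(0, 1), each = 4), ncol = 1)
  expect_lte(silhouette_score(co, rep(c(1, 2), 4)), 0)
  # far-separated tight clusters approach 1
  far <- matrix(c(0, 0.01, 1e4, 1e4 + 0.01), ncol = 1)
  expect_gt(silhouette_score(far, c(1, 1, 2, 2)), 0.999)
  expect_error(silhouette_score(pts, rep(1, 4)), "2 clusters")
})

test_that("both indices agree with brute-force oracles on random instances", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    d <- sample(1:5, 1)
    k <- sample(2:4, 1)
    pts <- matrix(rnorm(n * d), n, d)
    labels <- sample(k, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    if (min(table(labels)) < 1) next
    expect_equal(calinski_harabasz(pts, labels), brute_ch(pts, labels),
                 tolerance = 1e-9)
    expect_equal(silhouette_score(pts, labels), brute_sil(pts, labels),
                 tolerance = 1e-9)
  }
})

test_that("classification metrics follow their definitions with absent denominators", {
  m <- classification_metrics(2, 1, 1, 0)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 2 / 3)
  p <- classification_metrics(3, 5, 0, 0)
  expect_equal(c(p$accuracy, p$recall, p$precision), c(1, 1, 1))
  q <- classification_metrics(0, 4, 0, 0)
  expect_true(is.na(q$precision))
  expect_false(is.nan(q$precision))
  expect_error(classification_metrics(0, 0, 0, 0), "all zero")
  expect_error(classification_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("gene-set evaluation returns one row per set and repeat, reproducibly", {
  m <- default_clean()
  sets <- list(one = m$gene_symbols[1:50], two = m$gene_symbols[1:50])
  ev <- evaluate_gene_sets(m, sets, k = 3, n_repeats = 3,
                           subsample_size = 120, seed = 3)
  expect_equal(nrow(ev), 6L)
  # identical gene sets score identically per repeat
  w <- reshape(ev, direction = "wide", idvar = "rep", timevar = "gene_set")
  expect_equal(w$ch_index.one, w$ch_index.two)
  expect_equal(w$silhouette.one, w$silhouette.two)
  ev2 <- evaluate_gene_sets(m, sets, k = 3, n_repeats = 3,
                            subsample_size = 120, seed = 3)
  expect_identical(ev, ev2)
  expect_error(evaluate_gene_sets(m, sets, k = 3, n_repeats = 1,
                                  subsample_size = 1e6, seed = 1), "exceeds")
})

test_that("top variable genes favour bimodal markers over constant stable genes", {
  m <- default_clean()
  corp <- default_corpus()
  tv <- top_variable_genes(m, 100)
  expect_length(tv, 100L)
  expect_length(intersect(tv, corp$truth$stable_gene_symbols), 0L)
})
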