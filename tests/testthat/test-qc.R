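# A clean 12-cell, 30-gene toy corpus where every cell passes every filter.
clean_toy <- function() {
  set.seed(5)
  counts <- matrix(rpois(12 * 30, 3) + 1, nrow = 12)  # every gene detected
  make_cm(counts, samples = rep(c("s1", "s2"), each = 6))
}

test_that("min-genes filter removes below, retains at, the detection floor", {
  counts <- matrix(0, 3, 250)
  counts[1, 1:199] <- 1      # 199 detected -> removed
  counts[2, 1:200] <- 1      # exactly 200 -> retained
  counts[3, 1:250] <- 1
  x <- make_cm(counts)
  st <- filter_cells_min_genes(x, 200)
  expect_equal(st$removed, "cell01")
  expect_equal(st$matrix$cell_ids, c("cell02", "cell03"))

  empty <- subset_cells(x, cells = integer(0))
  st0 <- filter_cells_min_genes(empty, 200)
  expect_equal(dim(st0$matrix)[1], 0L)
  expect_length(st0$removed, 0L)
})

test_that("sample filter drops samples below the surviving-cell floor", {
  x <- make_cm(matrix(1, 5, 4), samples = c("a", "a", "a", "b", "b"))
  st <- filter_samples_min_cells(x, 3)
  expect_equal(st$removed_samples, "b")
  expect_equal(unique(st$matrix$sample_of_cell), "a")
  # exactly at the floor -> retained
  st2 <- filter_samples_min_cells(x, 2)
  expect_length(st2$removed_samples, 0L)
  # all samples below the floor -> empty matrix with warning
  expect_warning(st3 <- filter_samples_min_cells(x, 10), "empty")
  expect_equal(dim(st3$matrix)[1], 0L)
})

test_that("coding filter pools protein-coding and miRNA biotypes", {
  counts <- matrix(0, 2, 60)
  counts[1, c(1:6, 14:60)] <- 1   # 6 coding + 47 other, no miRNA
  counts[2, 7:13] <- 1            # 7 miRNA only
  x <- make_cm(counts)
  ann <- make_ann(x$gene_symbols,
                  biotype = c(rep("protein_coding", 6), rep("miRNA", 7),
                              rep("other", 47)))
  st <- filter_cells_coding(x, ann, 7)
  expect_equal(st$removed, "cell01")
  expect_equal(st$matrix$cell_ids, "cell02")

  # no annotated coding genes: everything fails, with a warning
  ann2 <- make_ann(x$gene_symbols, biotype = "other")
  expect_warning(st2 <- filter_cells_coding(x, ann2, 1), "every cell")
  expect_equal(dim(st2$matrix)[1], 0L)
})

test_that("mito filter is strict at the threshold and handles no-mito corpora", {
  counts <- rbind(c(16, 84), c(15, 85), c(10, 90))
  x <- make_cm(counts)
  ann <- make_ann(x$gene_symbols, mito = c(TRUE, FALSE))
  st <- filter_cells_mito(x, ann, 0.15)
  expect_equal(st$removed, "cell01")          # 16% > 15% removed
  expect_true("cell02" %in% st$matrix$cell_ids)  # exactly 15% retained

  ann2 <- make_ann(x$gene_symbols, mito = FALSE)
  st2 <- filter_cells_mito(x, ann2, 0.15)
  expect_length(st2$removed, 0L)
})

test_that("outlier filter trims the upper tail per sample, derived from mean/SD", {
  # 10 cells detecting 10 genes, one detecting 500
  counts <- matrix(0, 11, 500)
  for (i in 1:10) counts[i, 1:10] <- 1
  counts[11, ] <- 1
  x <- make_cm(counts)
  det <- c(rep(10, 10), 500)
  cut <- mean(det) + 3 * sd(det)
  st <- filter_cells_outlier(x, 3)
  if (500 > cut) {
    expect_equal(st$removed, "cell11")
  } else {
    expect_length(st$removed, 0L)
  }
  # identical cells: SD 0, nothing removed
  st2 <- filter_cells_outlier(make_cm(matrix(1, 5, 3)), 3)
  expect_length(st2$removed, 0L)
  # one-cell sample skips the stage
  st3 <- filter_cells_outlier(make_cm(matrix(1, 1, 3)), 3)
  expect_length(st3$removed, 0L)
})

test_that("core-gene restriction intersects preserving order and errors on disjoint lists", {
  x <- make_cm(matrix(1, 2, 5))
  st <- restrict_core_genes(x, c("g04", "g01", "g03"))
  expect_equal(st$matrix$gene_symbols, c("g01", "g03", "g04"))  # matrix order
  expect_equal(st$removed_genes, c("g02", "g05"))
  st2 <- restrict_core_genes(x, x$gene_symbols)
  expect_length(st2$removed_genes, 0L)
  expect_error(restrict_core_genes(x, c("nope")), "no genes")
  expect_error(restrict_core_genes(x, character(0)), "empty")
})

test_that("rare-type filter drops below, keeps at, the type floor", {
  x <- make_cm(matrix(1, 39, 3))
  labs <- setNames(c(rep("A", 19), rep("B", 20)), x$cell_ids)
  st <- filter_rare_cell_types(x, labs, 20)
  expect_setequal(st$removed, x$cell_ids[1:19])
  # unlabeled cells untouched, with a warning
  labs2 <- labs[-1]
  expect_warning(st2 <- filter_rare_cell_types(x, labs2, 20), "lack")
  expect_true("cell01" %in% st2$matrix$cell_ids)
})

test_that("staged removals equal the planted violation roster exactly", {
  corp <- default_corpus()
  rem <- qc_removals(corp$matrix, corp$annotation)
  truth <- corp$truth$qc_violations
  for (stage in names(truth)) {
    expect_setequal(rem[[stage]], truth[[stage]])
  }
})

test_that("run_qc accounts attrition consistently and is idempotent", {
  corp <- default_corpus()
  res <- run_qc(corp$matrix, corp$annotation)
  stg <- res$report$stages
  expect_equal(stg$after, stg$before - stg$removed)
  expect_equal(stg$before[-1], stg$after[-nrow(stg)])
  expect_equal(stg$before[1], nrow(corp$matrix$counts))
  expect_equal(stg$after[nrow(stg)], nrow(res$matrix$counts))

  twice <- run_qc(res$matrix, corp$annotation)
  expect_equal(sum(twice$report$stages$removed), 0)
  expect_identical(twice$matrix$cell_ids, res$matrix$cell_ids)
})

test_that("run_qc on an all-clean corpus is the identity", {
  x <- clean_toy()
  ann <- make_ann(x$gene_symbols)
  res <- run_qc(x, ann, qc_config(min_genes_per_cell = 10,
                                  min_coding_genes_per_cell = 5))
  expect_equal(sum(res$report$stages$removed), 0)
  expect_identical(res$matrix$cell_ids, x$cell_ids)
})

test_that("cell-level filters commute pairwise when no sample is deleted", {
  corp <- default_corpus()
  x <- corp$matrix; ann <- corp$annotation
  ab <- filter_cells_mito(filter_cells_min_genes(x, 200)$matrix, ann, 0.15)$matrix
  ba <- filter_cells_min_genes(filter_cells_mito(x, ann, 0.15)$matrix, 200)$matrix
  expect_identical(ab$cell_ids, ba$cell_ids)

  cd <- filter_cells_coding(filter_cells_min_genes(x, 200)$matrix, ann, 7)$matrix
  dc <- filter_cells_min_genes(filter_cells_coding(x, ann, 7)$matrix, 200)$matrix
  expect_identical(cd$cell_ids, dc$cell_ids)
})

test_that("core-gene stage works inside the cascade", {
  corp <- default_corpus()
  core <- corp$matrix$gene_symbols[1:500]
  res <- run_qc(corp$matrix, corp$annotation,
                qc_config(core_gene_list = core))
  expect_equal(ncol(res$matrix$counts), 500L)
  expect_setequal(res$report$genes_removed,
                  setdiff(corp$matrix$gene_symbols, core))
})

test_that("qc report TSV has the stage/before/removed/after schema", {
  corp <- default_corpus()
  res <- run_qc(corp$matrix, corp$annotation)
  p <- tempfile(fileext = ".tsv")
  write_qc_report(res$report, p)
  tab <- read.delim(p)
  expect_equal(names(tab), c("stage", "before", "removed", "after"))
  expect_equal(nrow(tab), nrow(res$report$stages))
})
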