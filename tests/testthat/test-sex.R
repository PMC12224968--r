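ratios_df <- function(x, y) {
  data.frame(sample_id = sprintf("s%d", seq_along(x)),
             x_ratio = x, y_ratio = y, stringsAsFactors = FALSE)
}

test_that("X/Y ratio statistics follow their definitions, with zero-denominator fallback", {
  # 1 sample: SRY FPKM 5 of chrY total 50; chrX-unique 30 of chrX 40
  vals <- matrix(c(5, 45, 30, 10), 1,
                 dimnames = list("s1", c("SRY", "Y2", "XU", "XO")))
  pb <- structure(list(values = vals, group_ids = "s1",
                       gene_symbols = colnames(vals), unit = "FPKM"),
                  class = "pseudobulk")
  ann <- gene_annotation(colnames(vals),
                         c("chrY", "chrY", "chrX", "chrX"),
                         "protein_coding",
                         is_chrX_unique = c(FALSE, FALSE, TRUE, FALSE))
  sr <- compute_sex_ratios(pb, ann, "SRY")
  expect_equal(sr$y_ratio, 0.1)
  expect_equal(sr$x_ratio, 0.75)

  # no chrY signal at all -> y_ratio 0
  pb0 <- pb; pb0$values[, c("SRY", "Y2")] <- 0
  expect_equal(compute_sex_ratios(pb0, ann, "SRY")$y_ratio, 0)

  expect_error(compute_sex_ratios(pb, ann, "Sry"), "absent")
  annx <- gene_annotation(colnames(vals), c("chr1", "chr1", "chrX", "chrX"),
                          "protein_coding",
                          is_chrX_unique = c(FALSE, FALSE, TRUE, FALSE))
  expect_error(compute_sex_ratios(pb, annx, "SRY"), "no chrY")
})

test_that("human classifier reproduces the published rule set", {
  th <- sex_thresholds("human")
  cases <- ratios_df(x = c(0.5, 0.3, 0.3, 0.0000005, 0.3),
                     y = c(0.002, 0.00005, 0.0005, 0.00005, 0.000106))
  got <- classify_sex(cases, th)$label
  expect_equal(got, c("male",      # y >= 0.001188 branch
                      "female",    # x >= 1e-6 and y <= 0.000106
                      "mixed",     # x > 0.00007, y inside the band
                      "unknown",   # x below the female floor
                      "female"))   # band edge belongs to the female branch
  # x at or below 0.00007 with y inside the band is male
  expect_equal(classify_sex(ratios_df(0.00007, 0.0005), th)$label, "male")
})

test_that("mouse classifier reproduces the published rule set", {
  th <- sex_thresholds("mouse")
  cases <- ratios_df(x = c(0.1, 0.1, 0.000008, 0.0001, 0.001, 0),
                     y = c(0.00007, 0.000002, 0.00003, 0.00003, 0.00003, 0.000001))
  got <- classify_sex(cases, th)$label
  expect_equal(got, c("male",      # y >= 0.000065
                      "female",    # x > 0 with y <= 0.000004
                      "male",      # x <= 0.000008 inside the band
                      "mixed",     # x between the two X cuts, y in band
                      "female",    # x >= 0.000555, y in band
                      "unknown"))  # no X signal, y below the band
})

test_that("every (x, y) pair receives exactly one of the four labels", {
  set.seed(31)
  xy <- cbind(c(runif(400), runif(200, 0, 0.002)),
              c(runif(400), runif(200, 0, 0.002)))
  for (sp in c("human", "mouse")) {
    lab <- classify_sex(ratios_df(xy[, 1], xy[, 2]), sex_thresholds(sp))$label
    expect_true(all(lab %in% c("male", "female", "mixed", "unknown")))
    expect_length(lab, nrow(xy))
  }
})

test_that("for fixed x, increasing y never moves a human call from male to female", {
  th <- sex_thresholds("human")
  for (x in c(0, 0.0000005, 0.00005, 0.0001, 0.3, 1)) {
    ys <- sort(c(seq(0, 0.002, length.out = 200), 0.000106, 0.001188))
    lab <- classify_sex(ratios_df(rep(x, length(ys)), ys), th)$label
    seen_male <- FALSE
    for (l in lab) {
      if (l == "male") seen_male <- TRUE
      if (seen_male) expect_false(l == "female")
    }
  }
})

test_that("NaN ratios classify as unknown with a warning", {
  expect_warning(out <- classify_sex(ratios_df(NaN, 0.5)), "unknown")
  expect_equal(out$label, "unknown")
})

test_that("sex correction replaces declarations and conserves the transition tally", {
  md <- sample_metadata(c("s1", "s2", "s3"),
                        declared_sex = c("unknown", "female", "male"))
  calls <- data.frame(sample_id = c("s1", "s2", "s3"),
                      label = c("male", "female", "female"))
  res <- correct_sample_sex(md, calls)
  expect_equal(res$samples$declared_sex, c("male", "female", "female"))
  expect_equal(nrow(res$corrections), 3L)      # one transition per sample
  expect_equal(res$corrections$matched_declaration, c(FALSE, TRUE, FALSE))
  expect_equal(res$corrections$original[1], "unknown")
  expect_equal(res$corrections$corrected[1], "male")
})

test_that("threshold calibration separates well-separated labeled samples", {
  sr <- ratios_df(x = rep(0.5, 8),
                  y = c(0.2, 0.21, 0.18, 0.25, 0, 0, 0.00001, 0.00002))
  known <- setNames(rep(c("male", "female"), each = 4), sr$sample_id)
  th <- calibrate_sex_thresholds(sr, known, "human")
  expect_equal(classify_sex(sr, th)$label, unname(known))
  expect_gt(th$male_y, 0.00002)
  expect_lt(th$male_y, 0.2)
})

test_that("classifier recovers every planted sex on the default corpus", {
  corp <- default_corpus()
  m <- default_clean()
  fpkm <- counts_to_fpkm(aggregate_pseudobulk(m, "sample"), corp$annotation)
  calls <- classify_sex(compute_sex_ratios(fpkm, corp$annotation, "SRY"),
                        sex_thresholds("human"))
  truth <- corp$truth$sex_of_sample[calls$sample_id]
  tc <- truth_confusion(setNames(calls$label, calls$sample_id), truth,
                        positive = "male")
  met <- classification_metrics(tc$TP, tc$TN, tc$FP, tc$FN)
  expect_gte(met$accuracy, 0.99)
  expect_equal(met$recall, 1)
  expect_equal(met$precision, 1)
})
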