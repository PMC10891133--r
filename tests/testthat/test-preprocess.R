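test_that("fragment filter drops only fragments missing in more than half the runs", {
  n_runs <- 74L
  x <- matrix(1000, 3, n_runs)
  x[1, 1:38] <- NA  # 38/74 > 1/2 -> removed
  x[2, 1:37] <- NA  # exactly half -> retained
  ft <- make_fragment_table(x)
  out <- filter_fragments(ft)
  expect_setequal(rownames(out$intensity), c("f02", "f03"))
  expect_equal(attr(out, "removed"), "f01")

  complete <- make_fragment_table(matrix(5, 4, 10))
  expect_equal(filter_fragments(complete)$intensity, complete$intensity)

  all_gone <- make_fragment_table(matrix(c(1, rep(NA, 9)), 1, 10))
  expect_error(filter_fragments(all_gone), "1/2")
})

test_that("kernel drift fit matches brute-force Nadaraya-Watson everywhere", {
  set.seed(42)
  n <- 19L
  md <- make_metadata(sprintf("R%02d", 1:n))
  x <- matrix(rnorm(3 * n, 20), 3, n,
              dimnames = list(c("a", "b", "c"), md$run_id))
  x[2, c(3, 7, 11)] <- NA
  dm <- fit_drift(x, md, kernel_sd = 5)
  for (i in 1:3) for (t in 1:n) {
    obs <- which(!is.na(x[i, ]))
    expect_equal(dm$trend[i, t], nw_oracle(t, obs, x[i, obs], 5),
                 tolerance = 1e-12)
  }
  expect_error(fit_drift(x, md, kernel_sd = 0), "positive")
})

test_that("kernel regression of a constant is the constant, and of two points midway their mean", {
  md <- make_metadata(c("R1", "R2", "R3"))
  x <- matrix(7, 1, 3, dimnames = list("a", md$run_id))
  dm <- fit_drift(x, md, kernel_sd = 5)
  expect_equal(unname(dm$trend[1, ]), rep(7, 3))

  x2 <- matrix(c(2, NA, 6), 1, 3, dimnames = list("a", md$run_id))
  dm2 <- fit_drift(x2, md, kernel_sd = 2)
  expect_equal(dm2$trend[1, "R2"], 4)  # symmetric weights
})

test_that("drift correction flattens a noiseless linear trend in the interior", {
  n <- 30L
  md <- make_metadata(sprintf("R%02d", 1:n))
  x <- matrix(10 + 0.1 * (1:n), 1, n, dimnames = list("a", md$run_id))
  dm <- fit_drift(x, md, kernel_sd = 5)
  corrected <- correct_drift(x, dm, md)
  interior <- corrected[1, 10:21]
  # residual wiggle is a small fraction of the 2.9-unit raw drift range
  expect_lt(diff(range(interior)), 0.05 * diff(range(x[1, ])))
  # centering preserves the fragment's observed mean level
  expect_equal(mean(corrected[1, ]), mean(x[1, ]), tolerance = 1e-10)
  # missingness preserved
  x[1, 5] <- NA
  dm <- fit_drift(x, md, kernel_sd = 5)
  out <- correct_drift(x, dm, md)
  expect_true(is.na(out[1, 5]) && !anyNA(out[1, -5]))
})

test_that("drift correction shrinks within-batch QC variance on drifting cohorts", {
  d <- small_design(drift_amplitude = 1.2, noise_sd_log2 = 0.1)
  co <- simulate_cohort(d)
  filt <- filter_fragments(co$fragments)
  log2i <- log2(filt$intensity)
  dm <- fit_drift(log2i, co$metadata, kernel_sd = 5)
  corr <- correct_drift(log2i, dm, co$metadata)
  qc_runs <- co$metadata$run_id[co$metadata$cohort == "qc"]
  v <- function(m, b) {
    rb <- intersect(qc_runs, co$metadata$run_id[co$metadata$batch == b])
    mean(apply(m[, rb], 1, var, na.rm = TRUE), na.rm = TRUE)
  }
  for (b in unique(co$metadata$batch))
    expect_lt(v(corr, b), v(log2i, b))
})

test_that("median equalization aligns batch medians and is idempotent", {
  md <- make_metadata(c("A1", "A2", "B1", "B2"), batch = c(1, 1, 2, 2),
                      run_order = c(1, 2, 1, 2))
  x <- matrix(c(9, 11, 11, 13, 9, 11, 11, 13), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), md$run_id))
  # batch medians 10 and 12 -> both shifted to 11
  out <- equalize_medians(x, md)
  expect_equal(median(out[, 1:2]), 11)
  expect_equal(median(out[, 3:4]), 11)
  expect_equal(equalize_medians(out, md), out)
  # single batch unchanged
  md1 <- make_metadata(c("A1", "A2"))
  x1 <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, md1$run_id))
  expect_equal(equalize_medians(x1, md1), x1)
  # back-transform returns the linear scale
  expect_equal(equalize_medians(x, md, back_transform = TRUE), 2^out)
})

test_that("median equalization leaves all batch medians equal on simulated data", {
  co <- simulate_cohort(small_design())
  log2i <- log2(filter_fragments(co$fragments)$intensity)
  out <- equalize_medians(log2i, co$metadata)
  meds <- sapply(unique(co$metadata$batch), function(b) {
    runs <- intersect(co$metadata$run_id[co$metadata$batch == b],
                      colnames(out))
    median(out[, runs], na.rm = TRUE)
  })
  expect_lt(diff(range(meds)), 1e-10)
})

test_that("fragment selection ranks by consensus correlation", {
  set.seed(1)
  n <- 20L
  shape <- sin(seq(0, 3, length.out = n))
  x <- rbind(2^(10 + shape), 2^(12 + shape), 2^(14 + shape),
             2^(11 - shape + rnorm(n, 0, 0.01)),
             2^(13 + shape + rnorm(n, 0, 0.01)),
             2^(15 + shape + rnorm(n, 0, 0.01)))
  ft <- make_fragment_table(x, protein = rep("P1", 6))
  sel <- select_fragments(ft, max_fragments = 5)
  expect_equal(sel$fragment_id[which.min(sel$score)], "f04")
  expect_false(sel$selected[sel$fragment_id == "f04"])

  # identical profiles: all scores 1, all retained
  ident <- make_fragment_table(rbind(2^shape * 16, 2^shape * 64,
                                     2^shape * 256),
                               protein = rep("P1", 3))
  sel2 <- select_fragments(ident, max_fragments = 3)
  expect_equal(sel2$score, rep(1, 3), tolerance = 1e-12)
  expect_true(all(sel2$selected))

  # scores equal a brute-force correlation with the median profile
  log2x <- log2(x)
  consensus <- apply(log2x, 2, median)
  for (i in 1:6) {
    got <- sel$score[sel$fragment_id == sprintf("f%02d", i)]
    expect_equal(got, cor(log2x[i, ], consensus), tolerance = 1e-12)
  }
})

test_that("proteins below the fragment minimum are kept and flagged", {
  x <- matrix(2^rnorm(3 * 8, 15), 3, 8)
  ft <- make_fragment_table(x, protein = c("P1", "P2", "P2"))
  sel <- select_fragments(ft, max_fragments = 5, min_fragments = 2)
  expect_true(all(sel$few_fragments[sel$protein == "P1"]))
  expect_false(any(sel$few_fragments[sel$protein == "P2"]))
  expect_true(all(sel$selected))
})

test_that("protein rollup is the log10 of summed selected intensities", {
  md <- make_metadata(c("R1", "R2"))
  x <- matrix(c(1000, NA, 100, 900), 2, 2,
              dimnames = list(c("f01", "f02"), c("R1", "R2")))
  ft <- make_fragment_table(x, protein = c("P1", "P1"))
  sel <- select_fragments(ft, max_fragments = 5)
  sel$selected <- TRUE  # too few runs for correlations; force both in
  pm <- rollup_proteins(ft, sel, md)
  expect_equal(unname(pm$protein["P1", "R1"]), 3)        # log10(1000 + NA)
  expect_equal(unname(pm$protein["P1", "R2"]), 3)        # log10(100 + 900)

  # all selected fragments missing -> missing
  x2 <- matrix(c(NA, NA, 10, 90), 2, 2,
               dimnames = list(c("f01", "f02"), c("R1", "R2")))
  ft2 <- make_fragment_table(x2, protein = c("P1", "P1"))
  pm2 <- rollup_proteins(ft2, sel, md)
  expect_true(is.na(pm2$protein["P1", "R1"]))
  expect_equal(unname(pm2$protein["P1", "R2"]), 2)
})

test_that("the full normalization run keeps dimensions and never imputes", {
  d <- cohort_design()
  co <- simulate_cohort(d)
  pm <- normalize_cohort(co$fragments, co$metadata)
  expect_equal(dim(pm$protein), c(334L, 58L))
  expect_equal(ncol(pm$qc), sum(co$metadata$cohort == "qc"))
  expect_equal(nrow(pm$provenance), 9L)

  # missingness propagates, never filled: a protein entirely unobserved in
  # a run can only be missing
  filt <- filter_fragments(co$fragments)
  sel_map <- split(filt$fragments$fragment_id, filt$fragments$protein)
  some <- names(sel_map)[1:25]
  for (p in some) {
    frag_obs <- colSums(!is.na(filt$intensity[sel_map[[p]], , drop = FALSE]))
    runs_all_missing <- names(frag_obs)[frag_obs == 0]
    runs_all_missing <- intersect(runs_all_missing, colnames(pm$protein))
    if (length(runs_all_missing))
      expect_true(all(is.na(pm$protein[p, runs_all_missing])))
  }
})
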