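test_that("metadata lays out matched pairs, batches, and interleaved QC runs", {
  md <- generate_metadata(cohort_design())
  subj <- md[md$cohort != "qc", ]
  expect_equal(nrow(subj), 58L)
  expect_equal(length(unique(md$batch)), 4L)
  expect_gt(sum(md$cohort == "qc"), 0L)
  # each pair occurs exactly twice with distinct cohorts and shared matching
  for (pid in unique(subj$pair_id)) {
    rows <- subj[subj$pair_id == pid, ]
    expect_equal(nrow(rows), 2L)
    expect_setequal(rows$cohort, c("control", "convalescent"))
    expect_equal(rows$age[1], rows$age[2])
    expect_equal(rows$sex[1], rows$sex[2])
    expect_equal(rows$race[1], rows$race[2])
  }
  # run_order unique within batch; QC rows carry no demographics
  for (b in unique(md$batch))
    expect_false(any(duplicated(md$run_order[md$batch == b])))
  qc <- md[md$cohort == "qc", ]
  expect_true(all(is.na(qc$age)) && all(is.na(qc$sex)) &&
                all(is.na(qc$titer)))
  # pair members are queued in succession
  for (b in unique(md$batch)) {
    mb <- md[md$batch == b, ]
    mb <- mb[order(mb$run_order), ]
    subj_idx <- which(mb$cohort != "qc")
    pids <- mb$pair_id[subj_idx]
    expect_true(all(pids[seq(1, length(pids), 2)] ==
                      pids[seq(2, length(pids), 2)]))
  }
})

test_that("a single pair yields exactly two subject records", {
  md <- generate_metadata(cohort_design(n_pairs = 1L, n_batches = 1L))
  subj <- md[md$cohort != "qc", ]
  expect_equal(nrow(subj), 2L)
  expect_equal(subj$pair_id[1], subj$pair_id[2])
  expect_setequal(subj$cohort, c("control", "convalescent"))
})

test_that("pairs not divisible across batches are distributed, never fail", {
  md <- generate_metadata(cohort_design(n_pairs = 5L, n_batches = 4L))
  per_batch <- table(md$batch[md$cohort != "qc"]) / 2
  expect_equal(sum(per_batch), 5)
  expect_lte(max(per_batch) - min(per_batch), 1)
})

test_that("same design and seed regenerate identical tables", {
  d <- small_design()
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$fragments$intensity, c2$fragments$intensity)
  expect_identical(c1$ptm$table, c2$ptm$table)
})

test_that("symptomatic cases have longer days since diagnosis and higher titers", {
  md <- generate_metadata(cohort_design(n_pairs = 200L))
  cases <- md[md$cohort == "convalescent", ]
  expect_gt(mean(cases$days_since_diagnosis[cases$symptoms]),
            mean(cases$days_since_diagnosis[!cases$symptoms]))
  expect_gt(mean(log10(cases$titer[cases$symptoms])),
            mean(log10(cases$titer[!cases$symptoms])))
})

test_that("days-titer squared correlation sits in the declared band around its target", {
  d <- cohort_design()
  expect_lt(abs(titer_days_r2(generate_metadata(d)) - d$r2_days_titer),
            d$r2_tolerance)
})

test_that("with drift and noise off, QC runs are identical within batch", {
  d <- small_design(drift_amplitude = 0, noise_sd_log2 = 0,
                    missing_rate = 0, censor_mid = -100)
  co <- simulate_cohort(d)
  qc_runs <- co$metadata$run_id[co$metadata$cohort == "qc"]
  for (b in unique(co$metadata$batch)) {
    rb <- intersect(qc_runs, co$metadata$run_id[co$metadata$batch == b])
    x <- co$fragments$intensity[, rb, drop = FALSE]
    expect_lt(max(apply(x, 1, function(v) diff(range(v)))), 1e-9)
  }
})

test_that("null designs carry exactly zero truth effects", {
  co <- simulate_cohort(small_design(frac_differential = 0))
  expect_true(all(co$fragments$truth$effects == 0))
})

test_that("injected effects are recovered by direct group averaging", {
  d <- cohort_design(n_pairs = 40L, effect_mean_log10 = 0.3,
                     effect_sd_log10 = 0, n_race_coupled = 0L,
                     noise_sd_log2 = 0.1, subject_sd_log2 = 0.2,
                     drift_amplitude = 0, missing_rate = 0,
                     censor_mid = -100, seed = 7L)
  co <- simulate_cohort(d)
  md <- co$metadata
  eff <- co$fragments$truth$effects
  log2i <- log2(co$fragments$intensity)
  case_runs <- md$run_id[md$cohort == "convalescent"]
  ctrl_runs <- md$run_id[md$cohort == "control"]
  for (p in names(eff)[eff != 0][1:5]) {
    idx <- co$fragments$fragments$protein == p
    obs_diff <- mean(log2i[idx, case_runs]) - mean(log2i[idx, ctrl_runs])
    expect_lt(abs(obs_diff - eff[p] * log2(10)), 0.15)
  }
})

test_that("flipping the effect direction negates truth and mirrors the data", {
  d_up <- small_design(frac_differential = 0.5, prob_up = 1,
                       missing_rate = 0, censor_mid = -100)
  d_dn <- small_design(frac_differential = 0.5, prob_up = 0,
                       missing_rate = 0, censor_mid = -100)
  md <- generate_metadata(d_up)
  up <- generate_fragments(d_up, md)
  dn <- generate_fragments(d_dn, generate_metadata(d_dn))
  expect_equal(up$truth$effects, -dn$truth$effects)
  # control and QC runs are untouched by the effect sign
  ctrl <- md$run_id[md$cohort != "convalescent"]
  expect_identical(up$intensity[, ctrl], dn$intensity[, ctrl])
  # the case-vs-control contrast mirrors around the shared baseline
  case <- md$run_id[md$cohort == "convalescent"]
  hctl <- md$run_id[md$cohort == "control"]
  contrast <- function(fr) {
    x <- log2(fr$intensity)
    rowMeans(x[, case], na.rm = TRUE) - rowMeans(x[, hctl], na.rm = TRUE)
  }
  eff_frag <- up$truth$effects[up$fragments$protein] * log2(10)
  expect_lt(max(abs((contrast(up) - contrast(dn)) / 2 - eff_frag),
                na.rm = TRUE), 1e-8)
})

test_that("PTM generator marks the configured shifted peptides", {
  d <- cohort_design()
  ptm <- generate_ptm_table(d, generate_metadata(d))
  expect_equal(length(ptm$truth$shift), 55L)
  expect_equal(sum(ptm$truth$shift != 0), 3L)
  no_shift <- generate_ptm_table(
    cohort_design(n_shifted_peptides = 0L),
    generate_metadata(cohort_design(n_shifted_peptides = 0L)))
  expect_true(all(no_shift$truth$shift == 0))
})
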