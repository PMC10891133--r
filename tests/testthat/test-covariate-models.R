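test_that("RATIO dataset is the paired log10 difference, recomputable by hand", {
  co <- simulate_cohort(small_design())
  pm <- normalize_cohort(co$fragments, co$metadata)
  ds <- build_datasets(pm$protein, co$metadata)
  pairs <- subject_pairs(co$metadata)
  for (k in seq_len(nrow(pairs))) {
    expect_equal(ds$RATIO$levels[, k],
                 pm$protein[, pairs$case_run[k]] -
                   pm$protein[, pairs$control_run[k]])
  }
  # identical case/control levels give an all-zero RATIO
  fake <- pm$protein
  fake[, pairs$case_run] <- fake[, pairs$control_run]
  expect_true(all(build_datasets(fake, co$metadata)$RATIO$levels == 0,
                  na.rm = TRUE))
  # CONTROL covariates carry the matched case's symptoms and days
  case_md <- co$metadata[match(pairs$case_run, co$metadata$run_id), ]
  expect_equal(ds$CONTROL$covariates$Symptoms, case_md$symptoms)
  expect_equal(ds$CONTROL$covariates$DaysSinceDiagnosis,
               case_md$days_since_diagnosis)
  # a missing run is a structural error naming the pair
  expect_error(build_datasets(pm$protein[, -1], co$metadata), "pair")
})

test_that("an exact linear response recovers its coefficient with p near 0", {
  co <- simulate_cohort(small_design(n_pairs = 15L))
  pm <- normalize_cohort(co$fragments, co$metadata)
  ds <- build_datasets(pm$protein, co$metadata)
  ds$COVID$levels["P001", ] <- 2 * ds$COVID$covariates$Age
  fits <- suppressWarnings(  # exact fit: summary.lm warns by design
    fit_models(ds, data.frame(dataset = "COVID", form = "univariate",
                              formula = "level ~ Age")))
  row <- fits[fits$protein == "P001", ]
  expect_equal(row$estimate, 2, tolerance = 1e-8)
  expect_lt(row$p, 1e-20)
})

test_that("OLS fits equal a brute-force normal-equations solve", {
  co <- simulate_cohort(small_design(n_pairs = 12L))
  pm <- normalize_cohort(co$fragments, co$metadata)
  ds <- build_datasets(pm$protein, co$metadata)
  spec <- data.frame(dataset = "RATIO", form = "multivariate",
                     formula = "level ~ Age + Sex + Symptoms")
  fits <- fit_models(ds, spec)
  for (p in unique(fits$protein)[1:5]) {
    y <- ds$RATIO$levels[p, ]
    X <- cbind(1, ds$RATIO$covariates$Age,
               as.integer(ds$RATIO$covariates$Sex == "male"),
               as.integer(ds$RATIO$covariates$Symptoms))
    ok <- complete.cases(cbind(y, X))
    beta <- solve(t(X[ok, ]) %*% X[ok, ], t(X[ok, ]) %*% y[ok])
    got <- fits[fits$protein == p, ]
    expect_equal(got$estimate[got$variable == "Age"], beta[2],
                 tolerance = 1e-8)
    expect_equal(got$estimate[got$variable == "Sex"], beta[3],
                 tolerance = 1e-8)
    expect_equal(got$estimate[got$variable == "Symptoms"], beta[4],
                 tolerance = 1e-8)
  }
})

test_that("univariate and multivariate coefficients agree under orthogonal covariates", {
  # constructed design: Age and Sex orthogonal by balance
  n <- 8L
  covar <- data.frame(pair_id = sprintf("PAIR%03d", 1:n),
                      Age = rep(c(30, 50), each = 4),
                      Sex = rep(c("male", "female"), 4),
                      Race = "white", Symptoms = FALSE,
                      DaysSinceDiagnosis = 10)
  set.seed(4)
  lv <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("P1", "P2"), NULL))
  ds <- list(COVID = list(levels = lv, covariates = covar))
  uni <- fit_models(ds, data.frame(dataset = "COVID", form = "univariate",
                                   formula = c("level ~ Age",
                                               "level ~ Sex")))
  multi <- fit_models(ds, data.frame(dataset = "COVID",
                                     form = "multivariate",
                                     formula = "level ~ Age + Sex"))
  for (p in c("P1", "P2")) for (v in c("Age", "Sex")) {
    expect_equal(
      uni$estimate[uni$protein == p & uni$variable == v],
      multi$estimate[multi$protein == p & multi$variable == v],
      tolerance = 1e-10)
  }
})

test_that("degenerate covariates are skipped with a reason, never crash", {
  n <- 6L
  covar <- data.frame(pair_id = sprintf("PAIR%03d", 1:n), Age = 40,
                      Sex = "male", Race = "white", Symptoms = TRUE,
                      DaysSinceDiagnosis = 20)
  lv <- matrix(rnorm(n), 1, n, dimnames = list("P1", NULL))
  ds <- list(COVID = list(levels = lv, covariates = covar))
  fits <- fit_models(ds, data.frame(dataset = "COVID", form = "univariate",
                                    formula = "level ~ Age"))
  expect_equal(nrow(fits), 0L)
  expect_equal(attr(fits, "skipped")$reason, "degenerate covariate")
})

test_that("an injected race-modulated effect surfaces in the RATIO race coefficient", {
  d <- cohort_design(n_pairs = 40L, frac_differential = 0.15,
                     effect_mean_log10 = 0.3, effect_sd_log10 = 0,
                     n_race_coupled = 8L, noise_sd_log2 = 0.15,
                     subject_sd_log2 = 0.2, seed = 5L)
  co <- simulate_cohort(d)
  pm <- normalize_cohort(co$fragments, co$metadata)
  ds <- build_datasets(pm$protein, co$metadata)
  fits <- fit_models(ds, data.frame(
    dataset = "RATIO", form = "multivariate",
    formula = "level ~ Age + Sex + Race + Symptoms + DaysSinceDiagnosis"))
  race <- fits[fits$variable == "Race", ]
  coupled <- co$fragments$truth$race_coupled
  med_p_coupled <- median(tapply(race$p, race$protein, min)[coupled])
  med_p_rest <- median(tapply(race$p, race$protein, min)[
    setdiff(unique(race$protein), coupled)])
  expect_lt(med_p_coupled, med_p_rest)
})

test_that("the significance grid maps tiers and dimensions correctly", {
  co <- simulate_cohort(small_design())
  pm <- normalize_cohort(co$fragments, co$metadata)
  diff <- paired_differential(pm$protein, co$metadata)
  ds <- build_datasets(pm$protein, co$metadata)
  fits <- fit_models(ds)
  grid <- significance_grid(fits, diff)
  expect_equal(dim(grid$directed), c(nrow(pm$protein), 11L))
  expect_equal(grid$directed[, "Overall"],
               setNames(diff$directed, diff$protein))
  # tier recomputable from the directed value
  p_back <- 1 - abs(grid$directed)
  expect_equal(grid$tier[!is.na(p_back) & p_back < 0.05],
               rep("primary", sum(p_back < 0.05, na.rm = TRUE)))
  expect_equal(directed_transform(0.10, 3), 0.90)
  expect_equal(significance_tier(0.10), "extended")
  expect_equal(significance_tier(0.50), "ns")
})
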