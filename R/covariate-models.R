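#' Assemble the three modeling datasets
#'
#' Splits the protein matrix into the healthy-control dataset (CONTROL),
#' the convalescent dataset (COVID), and the paired log-ratio dataset
#' (RATIO = `level(case) - level(control)` on the log10 scale, one column
#' per pair). Each dataset carries a covariate table with Age, Sex, Race,
#' Symptoms, and DaysSinceDiagnosis. In CONTROL, Symptoms and
#' DaysSinceDiagnosis are copied from the matched convalescent: they are
#' meaningless for healthy subjects and are included purely as negative
#' controls of the modeling framework. Titer is never a model variable.
#'
#' @param protein_matrix proteins x subject-run log10 matrix.
#' @param metadata run metadata.
#' @return List with elements `CONTROL`, `COVID`, `RATIO`, each a list of
#'   `levels` (protein matrix) and `covariates` (data frame, one row per
#'   column of `levels`).
#' @export
build_datasets <- function(protein_matrix, metadata) {
  pairs <- subject_pairs(metadata)
  miss <- setdiff(c(pairs$case_run, pairs$control_run),
                  colnames(protein_matrix))
  if (length(miss) > 0L)
    stop("runs of pair(s) missing from the protein matrix: ",
         paste(pairs$pair_id[pairs$case_run %in% miss |
                               pairs$control_run %in% miss],
               collapse = ", "))
  case_md <- metadata[match(pairs$case_run, metadata$run_id), ]
  covar <- data.frame(
    pair_id = pairs$pair_id,
    Age = case_md$age,
    Sex = case_md$sex,
    Race = case_md$race,
    Symptoms = case_md$symptoms,
    DaysSinceDiagnosis = case_md$days_since_diagnosis)
  case_levels <- protein_matrix[, pairs$case_run, drop = FALSE]
  control_levels <- protein_matrix[, pairs$control_run, drop = FALSE]
  list(
    CONTROL = list(levels = control_levels, covariates = covar),
    COVID = list(levels = case_levels, covariates = covar),
    RATIO = list(levels = case_levels - control_levels, covariates = covar))
}

#' The default six-model specification grid
#'
#' Three univariate families (one per dataset, each variable modeled
#' separately) and three multivariate families (all five variables jointly;
#' the RATIO multivariate model additionally includes the Age x Sex
#' interaction).
#'
#' @return Data frame with `dataset`, `form` (`univariate` /
#'   `multivariate`), and `formula` strings.
#' @export
default_model_specs <- function() {
  vars <- c("Age", "Sex", "Race", "Symptoms", "DaysSinceDiagnosis")
  uni <- expand.grid(dataset = c("CONTROL", "COVID", "RATIO"),
                     variable = vars, stringsAsFactors = FALSE)
  uni <- data.frame(dataset = uni$dataset, form = "univariate",
                    formula = paste("level ~", uni$variable))
  multi <- data.frame(
    dataset = c("CONTROL", "COVID", "RATIO"),
    form = "multivariate",
    formula = c(
      "level ~ Age + Sex + Race + Symptoms + DaysSinceDiagnosis",
      "level ~ Age + Sex + Race + Symptoms + DaysSinceDiagnosis",
      "level ~ Age + Sex + Race + Symptoms + DaysSinceDiagnosis + Age:Sex"))
  rbind(uni, multi)
}

#' Fit the linear-regression model families per protein
#'
#' Ordinary least squares of each protein's levels (or paired log ratios)
#' on the demographic covariates, with two-tailed t-tests on the
#' coefficients. Sex and Symptoms enter as 0/1 indicators, Race as
#' indicator contrasts against its most frequent level. Rows with missing
#' response or covariates are dropped per protein; proteins whose design
#' becomes rank-deficient (e.g. a single-level factor after filtering) are
#' skipped for that model with a logged reason. Benjamini-Hochberg
#' adjustment is applied within each (dataset, form, term) family across
#' proteins.
#'
#' @param datasets output of [build_datasets()].
#' @param specs model grid, default [default_model_specs()].
#' @return Data frame of class `model_fits`: `protein`, `dataset`, `form`,
#'   `variable` (model variable the term belongs to), `term`, `estimate`,
#'   `p`, `p_adj`, `n`. Skipped fits are recorded in attribute `skipped`.
#' @export
fit_models <- function(datasets, specs = default_model_specs()) {
  out <- list()
  skipped <- list()
  for (s in seq_len(nrow(specs))) {
    ds <- datasets[[specs$dataset[s]]]
    covar <- encode_covariates(ds$covariates)
    fm <- stats::as.formula(specs$formula[s])
    vars_used <- all.vars(fm)[-1]
    for (prot in rownames(ds$levels)) {
      df <- cbind(level = ds$levels[prot, ], covar)
      df <- df[stats::complete.cases(df[, c("level", vars_used)]), ,
               drop = FALSE]
      # factors must keep >= 2 levels after filtering
      for (v in vars_used)
        if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
      degenerate <- any(vapply(vars_used, function(v)
        length(unique(df[[v]])) < 2L, logical(1)))
      n_coef_needed <- length(vars_used) + 1L
      if (nrow(df) <= n_coef_needed || degenerate) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          protein = prot, dataset = specs$dataset[s], form = specs$form[s],
          formula = specs$formula[s],
          reason = if (degenerate) "degenerate covariate" else "too few rows")
        next
      }
      fit <- stats::lm(fm, data = df)
      sm <- summary(fit)$coefficients
      terms <- setdiff(rownames(sm), "(Intercept)")
      if (length(terms) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        protein = prot, dataset = specs$dataset[s], form = specs$form[s],
        variable = term_variable(terms, vars_used),
        term = terms,
        estimate = sm[terms, "Estimate"],
        p = sm[terms, "Pr(>|t|)"],
        n = nrow(df), row.names = NULL)
    }
  }
  fits <- do.call(rbind, out)
  if (is.null(fits))
    fits <- data.frame(protein = character(0), dataset = character(0),
                       form = character(0), variable = character(0),
                       term = character(0), estimate = numeric(0),
                       p = numeric(0), n = integer(0))
  # BH within each (dataset, form, term) family across proteins
  fits$p_adj <- if (nrow(fits) == 0L) numeric(0) else
    stats::ave(fits$p, interaction(fits$dataset, fits$form, fits$term,
                                   drop = TRUE), FUN = bh_adjust)
  attr(fits, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else NULL
  class(fits) <- c("model_fits", class(fits))
  fits
}

encode_covariates <- function(covar) {
  out <- covar
  out$Sex <- as.integer(covar$Sex == "male")
  out$Symptoms <- as.integer(as.logical(covar$Symptoms))
  if (!is.null(covar$Race)) {
    ref <- names(sort(table(covar$Race), decreasing = TRUE))[1]
    out$Race <- stats::relevel(factor(covar$Race), ref = ref)
  }
  out
}

term_variable <- function(terms, vars_used) {
  vapply(terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) return("Age:Sex")
    hit <- vars_used[startsWith(tm, vars_used)]
    if (length(hit) == 0L) tm else hit[which.max(nchar(hit))]
  }, character(1))
}

#' Significance grid of directed values across comparisons
#'
#' The display table behind per-protein significance heatmaps: one row per
#' protein, one column per comparison (the overall paired difference plus
#' each model variable in the CONTROL and COVID multivariate models), each
#' cell holding the directed value `+-(1 - p_adj)` signed by the
#' coefficient (or fold change). A companion tier grid classifies each
#' cell as `primary` (< 0.05), `extended` (< 0.20), or `ns`.
#'
#' @param fits a `model_fits` table.
#' @param diff_results a `differential_result`.
#' @param alpha,alpha_extended tier thresholds.
#' @return List with matrices `directed` and `tier` (proteins x
#'   comparisons).
#' @export
significance_grid <- function(fits, diff_results, alpha = 0.05,
                              alpha_extended = 0.20) {
  proteins <- diff_results$protein
  multi <- fits[fits$form == "multivariate" &
                  fits$dataset %in% c("CONTROL", "COVID") &
                  fits$variable != "Age:Sex", ]
  vars <- c("Age", "Sex", "Race", "Symptoms", "DaysSinceDiagnosis")
  cols <- c("Overall",
            paste(rep(c("CONTROL", "COVID"), each = length(vars)),
                  vars, sep = "."))
  directed <- matrix(NA_real_, length(proteins), length(cols),
                     dimnames = list(proteins, cols))
  directed[, "Overall"] <- diff_results$directed
  for (ds in c("CONTROL", "COVID")) {
    for (v in vars) {
      sub <- multi[multi$dataset == ds & multi$variable == v, ]
      if (nrow(sub) == 0L) next
      # multi-level factors contribute several terms; keep the most
      # significant contrast per protein
      best <- sub[order(sub$protein, sub$p_adj), ]
      best <- best[!duplicated(best$protein), ]
      idx <- match(proteins, best$protein)
      directed[, paste(ds, v, sep = ".")] <-
        directed_transform(best$p_adj[idx], best$estimate[idx])
    }
  }
  tier <- matrix(significance_tier(1 - abs(directed), alpha, alpha_extended),
                 nrow = length(proteins), dimnames = dimnames(directed))
  list(directed = directed, tier = tier)
}
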