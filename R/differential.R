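#' Paired t-test of protein levels across matched pairs
#'
#' For every protein, the paired differences
#' `d_i = level(case_i) - level(control_i)` on the log10 scale are tested
#' with a two-tailed paired (one-sample) t-test: `t = mean(d) / (sd(d) /
#' sqrt(n))`, p from the Student t distribution with `n - 1` degrees of
#' freedom. Pairs with either member missing are dropped per protein
#' (pairwise-complete pairing); proteins with fewer than `min_pairs`
#' complete pairs get missing results. Zero-variance difference vectors are
#' flagged and their p-value floored at the smallest representable double
#' rather than reported as 0.
#'
#' @param protein_matrix proteins x subject-run matrix of log10 levels.
#' @param pairs data frame from [subject_pairs()].
#' @param min_pairs minimum complete pairs required (default 3).
#' @return Data frame: `protein`, `n_pairs_used`, `log10_fc` (mean paired
#'   difference, convalescent - control), `t`, `p`, `zero_variance`.
#' @export
paired_test <- function(protein_matrix, pairs, min_pairs = 3L) {
  case <- protein_matrix[, pairs$case_run, drop = FALSE]
  control <- protein_matrix[, pairs$control_run, drop = FALSE]
  d <- case - control
  n <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  s <- apply(d, 1, stats::sd, na.rm = TRUE)
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  zero_var <- !is.na(s) & s == 0 & n >= min_pairs
  p[zero_var & m != 0] <- .Machine$double.xmin
  p[zero_var & m == 0] <- 1
  tstat[zero_var] <- NA_real_
  low_n <- n < min_pairs
  m[low_n] <- NA_real_
  p[low_n] <- NA_real_
  tstat[low_n] <- NA_real_
  data.frame(protein = rownames(protein_matrix), n_pairs_used = n,
             log10_fc = m, t = tstat, p = p, zero_variance = zero_var,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment with missing-value handling
#'
#' Step-up FDR adjustment over the non-missing p-values (one family);
#' missing entries are excluded from the family size and restored as
#' missing.
#'
#' @param pvals numeric p-values in `[0, 1]`, possibly with `NA`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Directed significance transform for ranking and display
#'
#' Maps an adjusted p-value and the sign of the fold change to the signed
#' quantity `(1 - p_adj)` (positive fold change) or `-(1 - p_adj)`
#' (negative). A fold change of exactly zero maps to 0.
#'
#' @param p_adj adjusted p-values in `[0, 1]`.
#' @param log10_fc fold changes whose sign directs the transform.
#' @return Signed values in `[-1, 1]`.
#' @export
directed_transform <- function(p_adj, log10_fc) {
  stopifnot(all(is.na(p_adj) | (p_adj >= 0 & p_adj <= 1)))
  sign(log10_fc) * (1 - p_adj)
}

#' Paired differential abundance with FDR tiers
#'
#' Runs [paired_test()], adjusts with [bh_adjust()] across all tested
#' proteins (a single family, matching a single volcano plot), computes the
#' directed transform, and assigns significance tiers: `primary`
#' (`p_adj < alpha`), `extended` (`p_adj < alpha_extended`), `ns`.
#'
#' @param protein_matrix proteins x subject runs, log10 levels.
#' @param metadata run metadata (pairing derived via [subject_pairs()]).
#' @param alpha primary tier threshold (default 0.05).
#' @param alpha_extended extended tier threshold (default 0.20).
#' @param min_pairs minimum complete pairs per protein (default 3).
#' @return Data frame of class `differential_result`: columns of
#'   [paired_test()] plus `p_adj`, `directed`, `tier`.
#' @export
paired_differential <- function(protein_matrix, metadata, alpha = 0.05,
                                alpha_extended = 0.20, min_pairs = 3L) {
  pairs <- subject_pairs(metadata)
  res <- paired_test(protein_matrix, pairs, min_pairs)
  res$p_adj <- bh_adjust(res$p)
  res$directed <- directed_transform(res$p_adj, res$log10_fc)
  res$tier <- significance_tier(res$p_adj, alpha, alpha_extended)
  class(res) <- c("differential_result", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "alpha_extended") <- alpha_extended
  res
}

#' Significance tier of an adjusted p-value
#'
#' `primary` below `alpha`, `extended` below `alpha_extended`, else `ns`.
#'
#' @param p_adj adjusted p-values.
#' @param alpha,alpha_extended tier thresholds (defaults 0.05, 0.20).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p_adj, alpha = 0.05, alpha_extended = 0.20) {
  tier <- rep(NA_character_, length(p_adj))
  ok <- !is.na(p_adj)
  tier[ok] <- "ns"
  tier[ok & p_adj < alpha_extended] <- "extended"
  tier[ok & p_adj < alpha] <- "primary"
  tier
}

#' Volcano-plot table with reliability flags
#'
#' One row per protein: fold change, `-log10` adjusted p, tier, and the QC
#' reliability flag (the "*" marking of less reliably quantified proteins).
#'
#' @param results a `differential_result` from [paired_differential()].
#' @param qc_report optional `qc_report` from [compute_cov()] supplying the
#'   flags; without it all flags are `NA`.
#' @return Data frame: `protein`, `log10_fc`, `neg_log10_p_adj`, `tier`,
#'   `unreliable`.
#' @export
volcano_table <- function(results, qc_report = NULL) {
  unreliable <- rep(NA, nrow(results))
  if (!is.null(qc_report)) {
    idx <- match(results$protein, qc_report$per_protein$protein)
    unreliable <- qc_report$per_protein$unreliable[idx]
  }
  data.frame(protein = results$protein, log10_fc = results$log10_fc,
             neg_log10_p_adj = -log10(results$p_adj), tier = results$tier,
             unreliable = unreliable, row.names = NULL)
}
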