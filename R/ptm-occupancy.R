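#' Modification level of a modified/unmodified peptide pair
#'
#' `log2(mod / (mod + unmod))`: the log2 occupancy fraction of the
#' modified form, a value in `(-Inf, 0]`. It is invariant to common
#' scaling of the two intensities. A modified intensity of 0 (or a pair
#' where both channels are 0 or either is missing) yields missing: a zero
#' modified signal is indistinguishable from a detection failure in DIA.
#'
#' @param mod,unmod non-negative linear intensities (vectorized).
#' @return Modification levels (log2 scale), `NA` where undefined.
#' @export
modification_level <- function(mod, unmod) {
  stopifnot(all(mod >= 0, na.rm = TRUE), all(unmod >= 0, na.rm = TRUE))
  lvl <- log2(mod / (mod + unmod))
  lvl[!is.na(lvl) & is.infinite(lvl)] <- NA_real_
  lvl[!is.na(lvl) & is.nan(lvl)] <- NA_real_
  lvl
}

#' Peptide x run matrix of modification levels
#'
#' @param ptm a `ptm_table` (see [generate_ptm_table()]) or its long data
#'   frame (`peptide`, `run_id`, `modified_intensity`,
#'   `unmodified_intensity`).
#' @return Matrix of modification levels, peptides x runs.
#' @export
ptm_level_matrix <- function(ptm) {
  tab <- if (inherits(ptm, "ptm_table")) ptm$table else ptm
  tab$level <- modification_level(tab$modified_intensity,
                                  tab$unmodified_intensity)
  peptides <- unique(tab$peptide)
  runs <- unique(tab$run_id)
  mat <- matrix(NA_real_, length(peptides), length(runs),
                dimnames = list(peptides, runs))
  mat[cbind(match(tab$peptide, peptides), match(tab$run_id, runs))] <-
    tab$level
  mat
}

#' Filter modified peptides by missingness of the modification level
#'
#' Removes peptides whose modification level is missing in strictly more
#' than `max_missing_frac` of the subject runs.
#'
#' @param level_matrix peptide x run matrix from [ptm_level_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction (default
#'   0.20).
#' @return The filtered matrix, with attribute `removed` naming dropped
#'   peptides.
#' @export
filter_ptm_peptides <- function(level_matrix, max_missing_frac = 0.20) {
  frac <- rowMeans(is.na(level_matrix))
  keep <- frac <= max_missing_frac
  if (!any(keep))
    stop("all modified peptides exceed the missingness threshold (",
         max_missing_frac, ")")
  out <- level_matrix[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(level_matrix)[!keep]
  out
}

#' Paired test of modification occupancy between cohorts
#'
#' Paired t-test of modification levels (convalescent minus matched
#' control, log2 scale) per peptide, BH-adjusted across peptides.
#'
#' @param level_matrix filtered peptide x run matrix of modification
#'   levels.
#' @param metadata run metadata (pairing via [subject_pairs()]).
#' @param min_pairs minimum complete pairs (default 3).
#' @param alpha,alpha_extended significance tier thresholds.
#' @return Data frame: `peptide`, `n_pairs_used`, `log2_fc`, `p`, `p_adj`,
#'   `tier`.
#' @export
test_occupancy <- function(level_matrix, metadata, min_pairs = 3L,
                           alpha = 0.05, alpha_extended = 0.20) {
  pairs <- subject_pairs(metadata)
  pairs <- pairs[pairs$case_run %in% colnames(level_matrix) &
                   pairs$control_run %in% colnames(level_matrix), ]
  res <- paired_test(level_matrix, pairs, min_pairs)
  names(res)[names(res) == "protein"] <- "peptide"
  names(res)[names(res) == "log10_fc"] <- "log2_fc"
  res$p_adj <- bh_adjust(res$p)
  res$tier <- significance_tier(res$p_adj, alpha, alpha_extended)
  res
}
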