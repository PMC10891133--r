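#' Remove fragments with excessive missingness
#'
#' Drops fragment ions whose intensity is missing in more than half of all
#' runs (subject and QC runs alike). A fragment missing in exactly half of
#' the runs is retained.
#'
#' @param fragments a `fragment_table` (see [generate_fragments()] or
#'   [read_fragment_table()]).
#' @return The filtered `fragment_table`, with attribute `removed` listing
#'   the dropped fragment ids.
#' @export
filter_fragments <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_table"))
  x <- fragments$intensity
  if (nrow(x) == 0L) stop("fragment table is empty")
  frac_missing <- rowMeans(is.na(x))
  keep <- frac_missing <= 0.5
  if (!any(keep))
    stop("all fragments missing in more than half of the runs ",
         "(threshold: missing fraction > 1/2)")
  out <- fragments
  out$intensity <- x[keep, , drop = FALSE]
  out$fragments <- fragments$fragments[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(x)[!keep]
  out
}

#' Fit per-batch run-order drift by Gaussian kernel regression
#'
#' For every fragment and batch, the time trend over run order is estimated
#' by Nadaraya-Watson regression with a Gaussian kernel of standard
#' deviation `kernel_sd` runs (full support, no truncation):
#' `trend(t) = sum_j w_j(t) x_j / sum_j w_j(t)` with
#' `w_j(t) = exp(-(t - t_j)^2 / (2 kernel_sd^2))` over the runs `j` of the
#' batch where the fragment is observed. Fragments with fewer than two
#' observed values in a batch get a constant trend equal to the batch mean
#' (or `NA` when entirely unobserved). QC runs participate like any other
#' run: they are interleaved precisely to capture drift.
#'
#' @param log2_mat fragments x runs matrix of log2 intensities (`NA` =
#'   missing).
#' @param metadata run metadata with `run_id`, `batch`, `run_order`.
#' @param kernel_sd kernel standard deviation in runs (default 5).
#' @return A `drift_model`: list with `trend` (matrix like `log2_mat`
#'   holding the fitted trend at every run position) and `kernel_sd`.
#' @export
fit_drift <- function(log2_mat, metadata, kernel_sd = 5) {
  if (!is.numeric(kernel_sd) || kernel_sd <= 0)
    stop("kernel_sd must be a positive number of runs")
  stopifnot(all(colnames(log2_mat) %in% metadata$run_id))
  trend <- log2_mat
  trend[] <- NA_real_
  for (b in unique(metadata$batch)) {
    runs <- metadata$run_id[metadata$batch == b]
    runs <- runs[runs %in% colnames(log2_mat)]
    t <- metadata$run_order[match(runs, metadata$run_id)]
    x <- log2_mat[, runs, drop = FALSE]
    obs <- !is.na(x)
    w <- exp(-outer(t, t, "-")^2 / (2 * kernel_sd^2))
    xz <- x
    xz[!obs] <- 0
    num <- xz %*% w
    den <- obs %*% w
    tr <- num / den
    n_obs <- rowSums(obs)
    few <- n_obs < 2L
    if (any(few)) {
      bmean <- rowSums(xz[few, , drop = FALSE]) /
        pmax(n_obs[few], 1L)
      bmean[n_obs[few] == 0L] <- NA_real_
      tr[few, ] <- bmean
    }
    trend[, runs] <- tr
  }
  structure(list(trend = trend, kernel_sd = kernel_sd),
            class = "drift_model")
}

#' Subtract the fitted run-order trend within each batch
#'
#' Each value becomes `value - trend(run_order) + center`, where `center` is
#' the mean of the fitted trend over the runs of the batch where the
#' fragment is observed. The centering keeps the fragment's within-batch
#' average level untouched, so drift correction removes the time trend
#' without re-scaling batches (batch alignment is the job of
#' [equalize_medians()]). Missing values stay missing.
#'
#' @param log2_mat matrix the drift was fitted on.
#' @param drift a `drift_model` from [fit_drift()].
#' @param metadata run metadata (for batch membership).
#' @return Corrected log2 matrix.
#' @export
correct_drift <- function(log2_mat, drift, metadata) {
  stopifnot(inherits(drift, "drift_model"))
  out <- log2_mat
  for (b in unique(metadata$batch)) {
    runs <- intersect(metadata$run_id[metadata$batch == b],
                      colnames(log2_mat))
    x <- log2_mat[, runs, drop = FALSE]
    tr <- drift$trend[, runs, drop = FALSE]
    obs <- !is.na(x)
    center <- rowSums(tr * obs, na.rm = TRUE) / pmax(rowSums(obs), 1L)
    out[, runs] <- x - tr + center
  }
  out
}

#' Equalize batch medians on the log scale
#'
#' Shifts every batch additively so its median over all observed values
#' equals the grand median of the per-batch medians, then (optionally)
#' returns to the linear scale. Applying the shift twice is a no-op.
#'
#' @param log2_mat fragments x runs log2 matrix.
#' @param metadata run metadata.
#' @param back_transform return `2^value` (linear scale) when `TRUE`.
#' @return Matrix on the log2 scale (default) or linear scale.
#' @export
equalize_medians <- function(log2_mat, metadata, back_transform = FALSE) {
  batches <- unique(metadata$batch)
  med <- vapply(batches, function(b) {
    runs <- intersect(metadata$run_id[metadata$batch == b],
                      colnames(log2_mat))
    stats::median(log2_mat[, runs], na.rm = TRUE)
  }, numeric(1))
  grand <- stats::median(med)
  out <- log2_mat
  for (k in seq_along(batches)) {
    runs <- intersect(metadata$run_id[metadata$batch == batches[k]],
                      colnames(log2_mat))
    out[, runs] <- log2_mat[, runs] + (grand - med[k])
  }
  if (back_transform) 2^out else out
}

#' Select quantification fragments per protein by profile agreement
#'
#' A transparent rollup-selection step: each fragment is scored by the
#' Pearson correlation of its log2 profile with the protein's median
#' fragment profile (median across the protein's fragments per run,
#' computed over runs observed in both). The `max_fragments` best-scoring
#' fragments are retained per protein; proteins with fewer than
#' `min_fragments` fragments keep everything they have and are flagged.
#' Fragments whose correlation is undefined (fewer than 3 shared
#' observations, or zero variance) score `-Inf` and rank last.
#'
#' @param fragments a `fragment_table` with normalized linear intensities.
#' @param max_fragments maximum fragments retained per protein (default 5).
#' @param min_fragments proteins with fewer observed fragments than this are
#'   flagged `few_fragments` (default 2).
#' @return Data frame with `protein`, `fragment_id`, `score`, `selected`,
#'   `few_fragments`.
#' @export
select_fragments <- function(fragments, max_fragments = 5L,
                             min_fragments = 2L) {
  stopifnot(inherits(fragments, "fragment_table"))
  log2i <- log2(replace_nonpositive(fragments$intensity))
  res <- lapply(split(seq_len(nrow(log2i)), fragments$fragments$protein),
                function(idx) {
    x <- log2i[idx, , drop = FALSE]
    consensus <- apply(x, 2, stats::median, na.rm = TRUE)
    score <- vapply(seq_len(nrow(x)), function(i)
      profile_cor(x[i, ], consensus), numeric(1))
    ord <- order(-score, idx)
    data.frame(
      protein = fragments$fragments$protein[idx][1],
      fragment_id = rownames(x)[ord],
      score = score[ord],
      selected = seq_along(ord) <= max_fragments,
      few_fragments = length(idx) < min_fragments)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

profile_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(-Inf)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(-Inf)
  stats::cor(x[ok], y[ok])
}

# log2 of a nonpositive intensity is an absence call in DIA exports
replace_nonpositive <- function(x) {
  x[!is.na(x) & x <= 0] <- NA_real_
  x
}

#' Roll fragments up to protein levels
#'
#' The protein level in a run is the log10 of the sum of the selected
#' fragments' linear intensities present in that run; a protein with all
#' selected fragments missing stays missing. Subject and QC runs are split
#' into parallel matrices.
#'
#' @param fragments normalized `fragment_table` (linear scale).
#' @param selection output of [select_fragments()].
#' @param metadata run metadata (to separate QC columns).
#' @return A list of class `protein_matrix`: `protein` (proteins x subject
#'   runs, log10), `qc` (proteins x QC runs, log10), `selection`, and
#'   `few_fragments` (named logical per protein).
#' @export
rollup_proteins <- function(fragments, selection, metadata) {
  sel <- selection[selection$selected, ]
  x <- replace_nonpositive(fragments$intensity)[sel$fragment_id, ,
                                                drop = FALSE]
  xz <- x
  xz[is.na(xz)] <- 0
  sums <- rowsum(xz, group = sel$protein)
  any_obs <- rowsum((!is.na(x)) * 1, group = sel$protein) > 0
  level <- log10(sums)
  level[!any_obs] <- NA_real_
  level[is.infinite(level)] <- NA_real_
  qc_runs <- intersect(colnames(level),
                       metadata$run_id[metadata$cohort == "qc"])
  subj_runs <- setdiff(colnames(level), qc_runs)
  flags <- tapply(selection$few_fragments, selection$protein, any)
  structure(list(
    protein = level[, subj_runs, drop = FALSE],
    qc = level[, qc_runs, drop = FALSE],
    selection = selection,
    few_fragments = flags[rownames(level)]
  ), class = "protein_matrix")
}

#' Run the full preprocessing chain
#'
#' Fixed, auditable order: missingness filter -> log2 -> per-batch kernel
#' drift fit and correction -> cross-batch median equalization ->
#' back-transform to linear -> fragment selection -> protein rollup ->
#' log10. No step imputes: the missingness pattern of the input is
#' preserved throughout.
#'
#' @param fragments raw `fragment_table` (linear intensities).
#' @param metadata run metadata.
#' @param kernel_sd drift kernel standard deviation in runs (default 5).
#' @param max_fragments,min_fragments fragment selection parameters (see
#'   [select_fragments()]).
#' @return A `protein_matrix` (see [rollup_proteins()]) with an added
#'   `provenance` element: one row per step with its parameters.
#' @export
normalize_cohort <- function(fragments, metadata, kernel_sd = 5,
                             max_fragments = 5L, min_fragments = 2L) {
  filtered <- filter_fragments(fragments)
  log2_mat <- log2(replace_nonpositive(filtered$intensity))
  drift <- fit_drift(log2_mat, metadata, kernel_sd)
  corrected <- correct_drift(log2_mat, drift, metadata)
  linear <- equalize_medians(corrected, metadata, back_transform = TRUE)
  normalized <- filtered
  normalized$intensity <- linear
  selection <- select_fragments(normalized, max_fragments, min_fragments)
  out <- rollup_proteins(normalized, selection, metadata)
  out$provenance <- data.frame(
    step = c("filter_fragments", "log2", "fit_drift", "correct_drift",
             "equalize_medians", "back_transform", "select_fragments",
             "rollup_proteins", "log10"),
    parameters = c(
      "max missing fraction 1/2",
      "nonpositive intensities treated as missing",
      sprintf("Gaussian kernel sd %.3g runs, Nadaraya-Watson, per batch",
              kernel_sd),
      "trend subtracted, batch-mean of trend restored",
      "additive shift to grand median of batch medians (log2 scale)",
      "2^x", sprintf("top %d fragments by consensus correlation, min %d",
                     max_fragments, min_fragments),
      "sum of selected linear intensities per run", "log10 of sum"))
  out$n_fragments_removed <- length(attr(filtered, "removed"))
  out
}
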