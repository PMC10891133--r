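#' Protein-level reliability from interleaved QC runs
#'
#' The coefficient of variation (CoV, percent) of each protein is computed
#' per batch on linear-scale QC levels (`10^log10`), using the sample
#' (n - 1) standard deviation, and averaged over the batches where it is
#' defined (at least two QC observations). Proteins whose average CoV
#' strictly exceeds `threshold_pct` are flagged as less reliably
#' quantified; the flag travels with every downstream result table.
#'
#' @param qc_matrix proteins x QC-run matrix of log10 levels (the `qc`
#'   element of a `protein_matrix`).
#' @param metadata run metadata.
#' @param threshold_pct reliability threshold on average CoV (default 50).
#' @return A list of class `qc_report`: `per_protein` (data frame with
#'   per-batch CoV columns, `avg_cov`, `unreliable`), `per_batch` (median
#'   CoV per batch), and `threshold_pct`.
#' @export
compute_cov <- function(qc_matrix, metadata, threshold_pct = 50) {
  qc_runs <- colnames(qc_matrix)
  if (length(qc_runs) == 0L) stop("no QC runs available for CoV computation")
  batch <- metadata$batch[match(qc_runs, metadata$run_id)]
  linear <- 10^qc_matrix
  batches <- sort(unique(batch))
  cov_b <- sapply(batches, function(b) {
    x <- linear[, batch == b, drop = FALSE]
    n <- rowSums(!is.na(x))
    cv <- 100 * apply(x, 1, stats::sd, na.rm = TRUE) /
      rowMeans(x, na.rm = TRUE)
    cv[n < 2L] <- NA_real_
    cv
  })
  cov_b <- matrix(cov_b, nrow = nrow(qc_matrix),
                  dimnames = list(rownames(qc_matrix),
                                  paste0("cov_batch", batches)))
  avg <- rowMeans(cov_b, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  per_protein <- data.frame(protein = rownames(qc_matrix), cov_b,
                            avg_cov = avg,
                            unreliable = !is.na(avg) & avg > threshold_pct,
                            row.names = NULL)
  per_batch <- data.frame(
    batch = batches,
    median_cov = apply(cov_b, 2, stats::median, na.rm = TRUE))
  structure(list(per_protein = per_protein, per_batch = per_batch,
                 threshold_pct = threshold_pct), class = "qc_report")
}

#' Pairwise correlations between QC runs at the fragment level
#'
#' Pearson correlations between all pairs of QC runs on raw linear fragment
#' intensities, pairwise-complete. Pairs with fewer than 3 shared fragments
#' (or zero variance) are reported as missing.
#'
#' @param fragments a `fragment_table` (raw linear intensities).
#' @param metadata run metadata.
#' @return List with `correlations` (data frame `run1`, `run2`, `r`) and
#'   `min` (minimum defined correlation, `NA` when none is defined).
#' @export
qc_correlations <- function(fragments, metadata) {
  qc_runs <- intersect(colnames(fragments$intensity),
                       metadata$run_id[metadata$cohort == "qc"])
  if (length(qc_runs) < 2L) stop("need at least two QC runs")
  x <- fragments$intensity[, qc_runs, drop = FALSE]
  pairs <- utils::combn(qc_runs, 2)
  r <- apply(pairs, 2, function(p) {
    cc <- profile_cor(x[, p[1]], x[, p[2]])
    if (is.infinite(cc)) NA_real_ else cc
  })
  correlations <- data.frame(run1 = pairs[1, ], run2 = pairs[2, ], r = r)
  list(correlations = correlations,
       min = if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
}

#' Two-component sample ordination (PCA or PLS-DA)
#'
#' Unsupervised overview by principal components, or supervised partial
#' least squares discriminant analysis using the cohort label as response.
#' Proteins with any missing value across the used samples are dropped
#' (their count is reported). Axis signs are fixed by forcing the loading
#' of largest magnitude on each component to be positive, so coordinates
#' are reproducible across platforms.
#'
#' @param protein_matrix proteins x samples matrix of log10 levels.
#' @param labels factor/character vector of sample labels (used as the
#'   response for PLS-DA; ignored by PCA except for reporting).
#' @param method `"pca"` or `"plsda"`.
#' @return List with `coordinates` (samples x 2), `explained_pct`
#'   (percent variance per component), `labels`, `n_proteins_used`,
#'   `n_proteins_dropped`.
#' @export
ordination <- function(protein_matrix, labels, method = c("pca", "plsda")) {
  method <- match.arg(method)
  if (ncol(protein_matrix) < 3L) stop("need at least 3 samples")
  complete <- stats::complete.cases(protein_matrix)
  x <- t(protein_matrix[complete, , drop = FALSE])
  if (ncol(x) < 2L) stop("fewer than 2 complete proteins")
  if (method == "pca") {
    fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    coords <- fit$x[, 1:2, drop = FALSE]
    load <- fit$rotation[, 1:2, drop = FALSE]
    expl <- 100 * fit$sdev[1:2]^2 / sum(fit$sdev^2)
  } else {
    fit <- mixOmics::plsda(x, factor(labels), ncomp = 2)
    coords <- fit$variates$X
    load <- fit$loadings$X
    expl <- 100 * fit$prop_expl_var$X[1:2]
  }
  # deterministic sign: largest-magnitude loading positive
  for (k in 1:2) {
    s <- sign(load[which.max(abs(load[, k])), k])
    if (s < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- c("comp1", "comp2")
  list(coordinates = coords, explained_pct = unname(expl),
       labels = labels, n_proteins_used = ncol(x),
       n_proteins_dropped = sum(!complete))
}
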