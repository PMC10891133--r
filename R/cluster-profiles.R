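#' Median-center protein rows
#'
#' Subtracts each protein's median over its observed values, the
#' standardization used for expression-signature heatmaps. Missing values
#' are preserved; the operation is idempotent.
#'
#' @param protein_matrix proteins x samples matrix.
#' @return Matrix of the same shape with row medians 0.
#' @export
median_center <- function(protein_matrix) {
  med <- apply(protein_matrix, 1, stats::median, na.rm = TRUE)
  sweep(protein_matrix, 1, med)
}

#' Correlation distance between protein profiles
#'
#' `d(x, y) = 1 - Pearson(x, y)` over pairwise-complete observations.
#' Pairs with an undefined correlation (fewer than 3 shared observations
#' or zero variance in either profile) get the maximal distance 2, so
#' degenerate rows remain placeable.
#'
#' @param mat proteins x samples matrix.
#' @return A `dist` object over the rows.
#' @export
pearson_distance <- function(mat) {
  r <- suppressWarnings(stats::cor(t(mat), use = "pairwise.complete.obs"))
  # count shared observations to invalidate correlations on < 3 points
  obs <- (!is.na(mat)) * 1
  shared <- obs %*% t(obs)
  r[shared < 3L] <- NA
  d <- 1 - r
  d[is.na(d)] <- 2
  diag(d) <- 0
  stats::as.dist(d)
}

#' Cluster protein expression signatures
#'
#' Agglomerative complete-linkage clustering on the `1 - Pearson`
#' correlation distance, cut into exactly `k` flat clusters. Rows with
#' fewer than `min_obs` observed values are dropped first (and logged in
#' the result), since their distances are undefined.
#'
#' @param centered_matrix median-centered proteins x samples matrix (see
#'   [median_center()]).
#' @param k number of flat clusters (default 20).
#' @param min_obs minimum observed values per row (default 3).
#' @return List of class `cluster_assignment`: `assignment` (data frame
#'   `protein`, `cluster`), `tree` (the `hclust` object), `dropped`
#'   (protein ids excluded for sparsity), `k`.
#' @export
cluster_profiles <- function(centered_matrix, k = 20L, min_obs = 3L) {
  keep <- rowSums(!is.na(centered_matrix)) >= min_obs
  mat <- centered_matrix[keep, , drop = FALSE]
  if (k < 1L || k > nrow(mat))
    stop("k must be between 1 and the number of clusterable rows (",
         nrow(mat), ")")
  tree <- stats::hclust(pearson_distance(mat), method = "complete")
  cl <- stats::cutree(tree, k = k)
  structure(list(
    assignment = data.frame(protein = rownames(mat), cluster = unname(cl),
                            row.names = NULL),
    tree = tree,
    dropped = rownames(centered_matrix)[!keep],
    k = k), class = "cluster_assignment")
}

#' Per-cluster significance summary
#'
#' For each cluster: member count, how many members reach the primary and
#' extended significance tiers of the overall comparison, whether any
#' member is significant, and the dominant direction (sign of the summed
#' fold changes of tiered members).
#'
#' @param assignment a `cluster_assignment`.
#' @param diff_results a `differential_result` on the same proteins.
#' @return Data frame, one row per cluster.
#' @export
summarize_clusters <- function(assignment, diff_results) {
  a <- assignment$assignment
  idx <- match(a$protein, diff_results$protein)
  a$tier <- diff_results$tier[idx]
  a$log10_fc <- diff_results$log10_fc[idx]
  res <- lapply(split(a, a$cluster), function(g) {
    sig <- g$tier %in% c("primary", "extended")
    data.frame(
      cluster = g$cluster[1],
      n_members = nrow(g),
      n_primary = sum(g$tier %in% "primary", na.rm = TRUE),
      n_extended = sum(sig, na.rm = TRUE),
      contains_significant = any(g$tier %in% "primary"),
      direction = sign(sum(g$log10_fc[sig], na.rm = TRUE)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Over-representation of gene sets within a cluster
#'
#' Hypergeometric test of each gene set's overlap with a cluster's members
#' against the clustered universe, BH-adjusted across sets. A lightweight
#' replacement for web-service function-enrichment of clusters.
#'
#' @param members character vector of cluster member identifiers.
#' @param universe all clustered identifiers.
#' @param gene_sets named list of identifier vectors.
#' @return Data frame: `set`, `overlap`, `set_size`, `p`, `p_adj`.
#' @export
cluster_enrichment <- function(members, universe, gene_sets) {
  sets <- lapply(gene_sets, intersect, universe)
  res <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    q <- length(intersect(members, s))
    data.frame(set = nm, overlap = q, set_size = length(s),
               p = stats::phyper(q - 1, length(s),
                                 length(universe) - length(s),
                                 length(members), lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p), ]
}
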