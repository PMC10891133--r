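# Small designs and hand-built fixtures shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_design <- function(n_pairs = 6L, n_batches = 2L, qc_interval = 3L,
                         n_proteins = 24L,
                         peptides_per_protein = c(1L, 2L),
                         fragments_per_peptide = c(2L, 3L),
                         n_race_coupled = 0L, n_mod_peptides = 12L,
                         n_shifted_peptides = 2L, seed = 11L, ...) {
  cohort_design(n_pairs = n_pairs, n_batches = n_batches,
                qc_interval = qc_interval, n_proteins = n_proteins,
                peptides_per_protein = peptides_per_protein,
                fragments_per_peptide = fragments_per_peptide,
                n_race_coupled = n_race_coupled,
                n_mod_peptides = n_mod_peptides,
                n_shifted_peptides = n_shifted_peptides, seed = seed, ...)
}

# fragment_table from an intensity matrix plus lineage
make_fragment_table <- function(intensity, peptide = NULL, protein = NULL) {
  n <- nrow(intensity)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("f%02d", seq_len(n))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("R%02d", seq_len(ncol(intensity)))
  structure(list(
    intensity = intensity,
    fragments = data.frame(
      fragment_id = rownames(intensity),
      peptide = peptide %||% rep("pep1", n),
      protein = protein %||% rep("P1", n)),
    truth = NULL), class = "fragment_table")
}

# minimal metadata for a hand-built run layout
make_metadata <- function(run_id, batch = 1L, run_order = seq_along(run_id),
                          cohort = "control") {
  data.frame(run_id = run_id, subject_id = run_id,
             pair_id = NA_character_, cohort = cohort, batch = batch,
             run_order = run_order, age = NA_real_, sex = NA_character_,
             race = NA_character_, symptoms = NA,
             days_since_diagnosis = NA_real_, titer = NA_real_)
}

# brute-force Nadaraya-Watson evaluation at one point
nw_oracle <- function(t_eval, t_obs, x_obs, sd) {
  w <- exp(-(t_eval - t_obs)^2 / (2 * sd^2))
  sum(w * x_obs) / sum(w)
}

# brute-force Benjamini-Hochberg step-up over all ranks
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# brute-force complete-linkage agglomeration with lowest-index tie-break;
# returns merge heights (sorted) and the flat partition at k clusters
complete_linkage_oracle <- function(d_mat, k) {
  n <- nrow(d_mat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d_mat[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  part <- integer(n)
  for (i in seq_along(clusters)) part[clusters[[i]]] <- i
  list(heights = heights, partition = part)
}

# partitions equal up to cluster relabeling
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
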