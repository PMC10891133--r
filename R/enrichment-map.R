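#' Ranked protein list from differential results
#'
#' Proteins ordered by descending directed adjusted p-value
#' (`+-(1 - p_adj)`); ties broken by protein identifier so the ranking --
#' and every permutation null built on it -- is reproducible. Proteins
#' without a directed value are dropped.
#'
#' @param diff_results a `differential_result`.
#' @return Named numeric vector of directed values, in ranking order.
#' @export
rank_list <- function(diff_results) {
  ok <- !is.na(diff_results$directed)
  v <- diff_results$directed[ok]
  names(v) <- diff_results$protein[ok]
  v[order(-v, names(v))]
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then members (tab-separated).
#' Duplicate members are removed.
#'
#' @param path path to the GMT file.
#' @return Named list of member vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of member vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Restrict gene sets to the ranked universe and by size
#'
#' Each set is intersected with the universe; sets whose intersection has
#' fewer than `min_size` or more than `max_size` members are excluded.
#'
#' @param sets named list of member vectors.
#' @param universe identifiers of the ranked list.
#' @param min_size,max_size inclusive size bounds (defaults 3 and 300).
#' @return Filtered list of universe-intersected sets.
#' @export
filter_sets <- function(sets, universe, min_size = 3L, max_size = 300L) {
  trimmed <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- vapply(trimmed, function(s)
    length(s) >= min_size && length(s) <= max_size, logical(1))
  if (!any(keep))
    stop("no gene set has between ", min_size, " and ", max_size,
         " members in the ranked universe")
  trimmed[keep]
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# in_set: logical over the ranked list; w: |ranking value|^exponent.
enrichment_score <- function(in_set, w) {
  n <- length(in_set)
  n_s <- sum(in_set)
  if (n_s == 0L || n_s == n) return(list(es = 0, peak = 0L))
  w_s <- sum(w[in_set])
  hit_step <- if (w_s > 0) w / w_s else rep(1 / n_s, n)
  step <- ifelse(in_set, hit_step, -1 / (n - n_s))
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak)
}

#' Preranked set enrichment with a permutation null
#'
#' Classic preranked set enrichment: the enrichment score (ES) of a set is
#' the signed maximum deviation of the weighted Kolmogorov-Smirnov running
#' sum over the ranked list, with weight exponent 1 on the absolute
#' ranking values. The null distribution comes from `n_perm` random
#' permutations of set membership over the ranked positions; the
#' permutation p-value is one-sided against the same-sign part of the
#' null, the normalized score NES divides ES by the mean same-sign null
#' magnitude, and the FDR q-value is the standard pooled-null ratio
#' estimator with monotonicity enforcement.
#'
#' @param ranks named numeric vector from [rank_list()].
#' @param sets filtered gene sets (see [filter_sets()]).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation null; if missing, a default
#'   of 1 is used with a warning, since reproducibility requires a seed.
#' @param exponent weight exponent on the absolute ranking value
#'   (default 1).
#' @return Data frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (comma-separated members).
#' @export
preranked_enrichment <- function(ranks, sets, n_perm = 1000L, seed = NULL,
                                 exponent = 1) {
  if (is.null(seed)) {
    warning("no seed supplied; using seed = 1 for the permutation null")
    seed <- 1L
  }
  set.seed(seed)
  ids <- names(ranks)
  n <- length(ids)
  w <- abs(ranks)^exponent
  obs <- lapply(sets, function(s) {
    in_set <- ids %in% s
    sc <- enrichment_score(in_set, w)
    le <- if (sc$es >= 0) ids[seq_len(sc$peak)][in_set[seq_len(sc$peak)]]
      else ids[sc$peak:n][in_set[sc$peak:n]]
    list(es = sc$es, size = sum(in_set), leading_edge = le)
  })
  sizes <- vapply(obs, `[[`, numeric(1), "size")
  # one shared null per distinct set size
  null_by_size <- lapply(unique(sizes), function(k) {
    vapply(seq_len(n_perm), function(i) {
      in_set <- logical(n)
      in_set[sample.int(n, k)] <- TRUE
      enrichment_score(in_set, w)$es
    }, numeric(1))
  })
  names(null_by_size) <- as.character(unique(sizes))

  es <- vapply(obs, `[[`, numeric(1), "es")
  p <- nes <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    denom_pos <- mean(nul[nul >= 0])
    denom_neg <- mean(abs(nul[nul < 0]))
    if (!is.finite(denom_pos) || denom_pos == 0) denom_pos <- 1
    if (!is.finite(denom_neg) || denom_neg == 0) denom_neg <- 1
    nes[i] <- if (es[i] >= 0) es[i] / denom_pos else -abs(es[i]) / denom_neg
    nn <- ifelse(nul >= 0, nul / denom_pos, -abs(nul) / denom_neg)
    null_nes[[i]] <- nn
  }
  pooled <- unlist(null_nes)
  q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pooled[pooled >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pooled[pooled < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (is.nan(num)) num <- 0
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  # q-value semantics: the q of a set is the best achievable FDR among
  # same-sign cutoffs that still retain it, so a more extreme NES never
  # carries a larger q
  for (sgn in c(1, -1)) {
    idx <- which(if (sgn == 1) nes >= 0 else nes < 0)
    if (length(idx) > 1L) {
      ord <- idx[order(abs(nes[idx]))]
      q[ord] <- cummin(q[ord])
    }
  }
  out <- data.frame(
    set = names(sets), size = sizes, es = es, nes = nes, p = p, q = q,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1)),
    row.names = NULL)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Build the Jaccard-linked enrichment map
#'
#' Nodes are sets passing the FDR cutoff (size attribute = number of
#' members in the ranked universe); an edge joins two nodes when the
#' Jaccard index of their universe-intersected member sets is at least
#' `jaccard_min` (boundary inclusive), carrying the index as weight.
#'
#' @param results an `enrichment_result`.
#' @param sets the filtered gene sets the results were computed on.
#' @param fdr_cutoff node retention threshold on q (default 0.01).
#' @param jaccard_min minimum Jaccard index for an edge (default 0.80).
#' @return List of class `enrichment_graph`: `nodes` (data frame `set`,
#'   `size`, `nes`, `q`) and `edges` (data frame `set1`, `set2`,
#'   `jaccard`).
#' @export
build_graph <- function(results, sets, fdr_cutoff = 0.01,
                        jaccard_min = 0.80) {
  keep <- results[!is.na(results$q) & results$q < fdr_cutoff, ]
  nodes <- data.frame(set = keep$set, size = keep$size, nes = keep$nes,
                      q = keep$q, row.names = NULL)
  edges <- data.frame(set1 = character(0), set2 = character(0),
                      jaccard = numeric(0))
  if (nrow(nodes) >= 2L) {
    cmb <- utils::combn(nodes$set, 2)
    jac <- apply(cmb, 2, function(p)
      jaccard_index(sets[[p[1]]], sets[[p[2]]]))
    sel <- jac >= jaccard_min
    edges <- data.frame(set1 = cmb[1, sel], set2 = cmb[2, sel],
                        jaccard = jac[sel], row.names = NULL)
  }
  structure(list(nodes = nodes, edges = edges), class = "enrichment_graph")
}

#' Jaccard index of two sets
#' @param a,b vectors of identifiers.
#' @return `|a intersect b| / |a union b|` (0 when both sets are empty).
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Simulate a gene-set collection over a protein universe
#'
#' Random sets drawn from the universe, optionally with one planted set
#' made of the top-ranked proteins (to which downstream enrichment should
#' assign the strongest signal).
#'
#' @param universe protein identifiers.
#' @param n_sets number of random sets.
#' @param size_range inclusive range of set sizes.
#' @param planted optional character vector used verbatim as set
#'   `"planted"`.
#' @param seed integer seed.
#' @return Named list of sets.
#' @export
simulate_gene_sets <- function(universe, n_sets = 25L,
                               size_range = c(5L, 40L), planted = NULL,
                               seed = 1L) {
  set.seed(seed)
  lo <- min(size_range[1], length(universe))
  hi <- min(size_range[2], length(universe))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(seq(lo, hi), 1)))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  if (!is.null(planted)) sets$planted <- planted
  sets
}
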