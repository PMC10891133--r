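#' Default stage parameters of the pipeline
#'
#' Every parameter defaults to the study's stated value where one exists:
#' drift kernel sd 5 runs, QC reliability threshold 50% CoV, significance
#' tiers 0.05 / 0.20, 20 profile clusters, 1000 enrichment permutations,
#' gene-set size bounds 3-300, enrichment-map FDR 0.01 and Jaccard 0.80,
#' PTM missingness threshold 20%.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(kernel_sd = 5, max_fragments = 5L, min_fragments = 2L,
       cov_threshold = 50, alpha = 0.05, alpha_extended = 0.20,
       min_pairs = 3L, k_clusters = 20L, n_perm = 1000L,
       min_set_size = 3L, max_set_size = 300L,
       fdr_cutoff = 0.01, jaccard_min = 0.80,
       ptm_max_missing = 0.20)
}

#' Run the cohort analysis end to end
#'
#' Orchestrates simulate (or ingest) -> normalize -> QC -> paired
#' differential -> covariate models -> profile clustering -> PTM occupancy
#' -> preranked enrichment map, writing every stage's table to `out_dir`
#' together with a `manifest.json` recording parameters, seeds, and
#' per-stage row counts. Rerunning with the same configuration reproduces
#' the outputs byte for byte.
#'
#' Reproduction mode: when `config$inputs` supplies a `protein_matrix`
#' path (protein x sample log10 levels) plus `metadata` (and optionally
#' `ptm`), the simulate and normalize stages are skipped and the
#' statistical stages run on the supplied tables.
#'
#' @param config list with elements `design` (a [cohort_design()]; used
#'   when simulating), `inputs` (optional list of file paths:
#'   `protein_matrix`, `metadata`, `ptm`), `gene_sets` (named list, GMT
#'   path, or `NULL` to simulate a collection), and `params` (overrides of
#'   [default_pipeline_params()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  simulate_mode <- is.null(config$inputs$protein_matrix)
  if (simulate_mode) {
    design <- config$design %||% cohort_design()
    cohort <- stage("simulate", simulate_cohort(design))
    metadata <- cohort$metadata
    write_tsv(metadata, file.path(out_dir, "metadata.tsv"))
    write_fragment_table(cohort$fragments,
                         file.path(out_dir, "fragments.tsv"))
    write_tsv(data.frame(protein = names(cohort$fragments$truth$effects),
                         effect_log10 = cohort$fragments$truth$effects),
              file.path(out_dir, "truth_effects.tsv"))
    pm <- stage("normalize",
                normalize_cohort(cohort$fragments, metadata,
                                 kernel_sd = params$kernel_sd,
                                 max_fragments = params$max_fragments,
                                 min_fragments = params$min_fragments))
    write_matrix_tsv(pm$protein, file.path(out_dir, "protein_matrix.tsv"))
    write_matrix_tsv(pm$qc, file.path(out_dir, "qc_matrix.tsv"))
    write_tsv(pm$provenance, file.path(out_dir, "provenance.tsv"))
    qc <- stage("qc", compute_cov(pm$qc, metadata, params$cov_threshold))
    write_tsv(qc$per_protein, file.path(out_dir, "qc_cov.tsv"))
    qc_corr <- stage("qc", qc_correlations(cohort$fragments, metadata))
    ptm_input <- cohort$ptm
  } else {
    metadata <- utils::read.delim(config$inputs$metadata,
                                  stringsAsFactors = FALSE)
    protein <- read_matrix_tsv(config$inputs$protein_matrix)
    pm <- list(protein = protein, qc = NULL)
    qc <- NULL
    qc_corr <- NULL
    ptm_input <- if (!is.null(config$inputs$ptm))
      utils::read.delim(config$inputs$ptm, stringsAsFactors = FALSE)
    else NULL
  }

  diff <- stage("differential",
                paired_differential(pm$protein, metadata,
                                    alpha = params$alpha,
                                    alpha_extended = params$alpha_extended,
                                    min_pairs = params$min_pairs))
  volc <- volcano_table(diff, qc)
  write_tsv(diff, file.path(out_dir, "differential.tsv"))
  write_tsv(volc, file.path(out_dir, "volcano.tsv"))

  datasets <- stage("models", build_datasets(pm$protein, metadata))
  fits <- stage("models", fit_models(datasets))
  write_tsv(fits, file.path(out_dir, "model_fits.tsv"))

  centered <- median_center(pm$protein)
  k <- min(params$k_clusters, nrow(centered))
  clust <- stage("cluster", cluster_profiles(centered, k = k))
  write_tsv(clust$assignment, file.path(out_dir, "clusters.tsv"))
  clust_sum <- summarize_clusters(clust, diff)
  write_tsv(clust_sum, file.path(out_dir, "cluster_summary.tsv"))

  ptm_res <- NULL
  if (!is.null(ptm_input)) {
    levels <- stage("ptm", ptm_level_matrix(ptm_input))
    levels <- stage("ptm",
                    filter_ptm_peptides(levels, params$ptm_max_missing))
    ptm_res <- stage("ptm", test_occupancy(levels, metadata,
                                           params$min_pairs,
                                           params$alpha,
                                           params$alpha_extended))
    write_tsv(ptm_res, file.path(out_dir, "ptm_occupancy.tsv"))
  }

  ranks <- rank_list(diff)
  gene_sets <- config$gene_sets
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.null(gene_sets))
    gene_sets <- simulate_gene_sets(
      names(ranks), seed = (config$design$seed %||% 1L) + 3L)
  sets <- stage("enrich", filter_sets(gene_sets, names(ranks),
                                      params$min_set_size,
                                      params$max_set_size))
  enr <- stage("enrich",
               preranked_enrichment(ranks, sets, n_perm = params$n_perm,
                                    seed = (config$design$seed %||% 1L) + 4L))
  graph <- build_graph(enr, sets, params$fdr_cutoff, params$jaccard_min)
  write_tsv(enr[, setdiff(names(enr), "leading_edge")],
            file.path(out_dir, "enrichment.tsv"))
  write_tsv(graph$nodes, file.path(out_dir, "enrichment_nodes.tsv"))
  write_tsv(graph$edges, file.path(out_dir, "enrichment_edges.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("diaserum")),
    mode = if (simulate_mode) "simulate" else "reproduction",
    seed = if (simulate_mode) (config$design %||% cohort_design())$seed
      else NA,
    parameters = params,
    stage_rows = list(
      runs = nrow(metadata),
      proteins = nrow(pm$protein),
      differential = nrow(diff),
      model_fits = nrow(fits),
      clusters = nrow(clust_sum),
      ptm_peptides = if (is.null(ptm_res)) 0L else nrow(ptm_res),
      enriched_sets = nrow(enr),
      graph_nodes = nrow(graph$nodes),
      graph_edges = nrow(graph$edges)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metadata = metadata, protein = pm, qc = qc,
                 qc_correlations = qc_corr, differential = diff,
                 volcano = volc, model_fits = fits, clusters = clust,
                 cluster_summary = clust_sum, ptm = ptm_res,
                 enrichment = enr, graph = graph, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
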