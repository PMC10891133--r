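#' Describe a synthetic matched-pair DIA serum cohort
#'
#' A `cohort_design` bundles every tunable of the synthetic data generator:
#' the cohort layout (matched case/control pairs, acquisition batches,
#' interleaved pooled QC injections), the fragment-level intensity model
#' (protein -> peptide -> fragment hierarchy with log-normal intensities,
#' smooth within-batch run-order drift, intensity-dependent missingness),
#' the injected case/control effects, the demographic couplings, and the
#' hexose-modified peptide channels.
#'
#' Defaults emulate a serum study of 29 COVID-19 convalescents and 29
#' age/sex/race-matched healthy controls acquired in 4 batches with a pooled
#' QC injection about every 6 subject runs, 334 quantified proteins of which
#' 37 carry a true effect (22 elevated, 15 lowered in convalescents), and
#' 55 hexose-modified peptides of which 3 carry a true occupancy shift.
#'
#' @param n_pairs number of case/control pairs (one convalescent plus one
#'   matched healthy control each).
#' @param n_batches number of acquisition batches; pairs are distributed as
#'   evenly as possible, remainder assigned to the earliest batches.
#' @param qc_interval number of subject runs between pooled QC injections
#'   (a QC run also opens and closes every batch); must be >= 2.
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (length 2) of peptides per
#'   protein, sampled uniformly.
#' @param fragments_per_peptide integer range (length 2) of fragment ions per
#'   peptide, sampled uniformly.
#' @param frac_differential fraction of proteins with a true case/control
#'   effect.
#' @param prob_up probability that a true effect is an elevation in
#'   convalescents (rather than a reduction).
#' @param effect_mean_log10,effect_sd_log10 mean and sd of the magnitude of
#'   true protein-level effects, in log10 units (convalescent - control).
#' @param n_race_coupled number of differential proteins whose effect is
#'   modulated by race (amplified in black, damped in other participants,
#'   leaving the race-averaged effect approximately unchanged); emulates the
#'   race-specific immunoglobulin signals seen in serum cohorts.
#' @param drift_amplitude peak-to-trough amplitude (log2 units) of the smooth
#'   within-batch run-order drift shared by all fragments up to a
#'   per-fragment sensitivity multiplier.
#' @param batch_sd_log2 sd of the additive per-batch offset (log2).
#' @param subject_sd_log2 sd of biological subject-by-protein variation
#'   (log2).
#' @param noise_sd_log2 sd of run-level fragment measurement noise (log2).
#' @param missing_rate baseline missingness probability per fragment per run;
#'   an intensity-dependent logistic component adds censoring of faint
#'   signals on top of it.
#' @param censor_mid,censor_scale midpoint (log2 intensity) and scale of the
#'   logistic low-intensity censoring component.
#' @param prob_symptomatic probability that a convalescent reported symptoms
#'   during the acute phase.
#' @param prob_male probability that a pair is male.
#' @param race_probs named probabilities of the race categories.
#' @param days_symptomatic,days_asymptomatic `c(mean, sd)` of days between
#'   diagnosis and sample collection for symptomatic and asymptomatic cases;
#'   truncated to `days_range`.
#' @param days_range admissible range of days since diagnosis.
#' @param titer_slope slope of latent log10 antibody titer on days since
#'   diagnosis.
#' @param titer_intercept intercept of the latent log10 titer model.
#' @param titer_noise_sd sd of the latent log10 titer around the linear
#'   trend; calibrated so that the squared correlation between days since
#'   diagnosis and log10 titer centers on `r2_days_titer`.
#' @param r2_days_titer design target for the squared Pearson correlation
#'   between days since diagnosis and log10 titer across cases.
#' @param r2_tolerance declared tolerance band around `r2_days_titer` for a
#'   single simulated cohort of default size.
#' @param titer_min_dilution lowest dilution of the titer assay; latent
#'   titers below it are reported as "no antibody response" with the
#'   sentinel value `titer_min_dilution / 2`.
#' @param n_mod_peptides number of hexose-modified peptide channels (each a
#'   modified/unmodified intensity pair per run).
#' @param n_shifted_peptides number of modified peptides with a true
#'   occupancy shift in convalescents.
#' @param occupancy_shift logit-scale shift of modification occupancy in
#'   convalescents for the shifted peptides.
#' @param ptm_missing_rate missingness probability per PTM intensity channel.
#' @param seed integer random seed; the generator is fully deterministic
#'   given the design (seed included).
#'
#' @return An object of class `cohort_design` (a named list).
#' @seealso [generate_metadata()], [generate_fragments()],
#'   [generate_ptm_table()], [simulate_cohort()]
#' @export
cohort_design <- function(n_pairs = 29L,
                          n_batches = 4L,
                          qc_interval = 6L,
                          n_proteins = 334L,
                          peptides_per_protein = c(1L, 3L),
                          fragments_per_peptide = c(2L, 4L),
                          frac_differential = 37 / 334,
                          prob_up = 22 / 37,
                          effect_mean_log10 = 0.2,
                          effect_sd_log10 = 0.05,
                          n_race_coupled = 6L,
                          drift_amplitude = 0.8,
                          batch_sd_log2 = 0.3,
                          subject_sd_log2 = 0.5,
                          noise_sd_log2 = 0.3,
                          missing_rate = 0.03,
                          censor_mid = 11,
                          censor_scale = 1.5,
                          prob_symptomatic = 15 / 29,
                          prob_male = 0.545,
                          race_probs = c(white = 0.45, black = 0.45,
                                         asian = 0.05, other = 0.05),
                          days_symptomatic = c(59, 11),
                          days_asymptomatic = c(32, 6),
                          days_range = c(9, 70),
                          titer_slope = 0.04,
                          titer_intercept = 0.41,
                          titer_noise_sd = 0.62,
                          r2_days_titer = 0.44,
                          r2_tolerance = 0.25,
                          titer_min_dilution = 50,
                          n_mod_peptides = 55L,
                          n_shifted_peptides = 3L,
                          occupancy_shift = 1.2,
                          ptm_missing_rate = 0.05,
                          seed = 1L) {
  design <- list(
    n_pairs = as.integer(n_pairs), n_batches = as.integer(n_batches),
    qc_interval = as.integer(qc_interval),
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    fragments_per_peptide = as.integer(fragments_per_peptide),
    frac_differential = frac_differential, prob_up = prob_up,
    effect_mean_log10 = effect_mean_log10,
    effect_sd_log10 = effect_sd_log10,
    n_race_coupled = as.integer(n_race_coupled),
    drift_amplitude = drift_amplitude, batch_sd_log2 = batch_sd_log2,
    subject_sd_log2 = subject_sd_log2, noise_sd_log2 = noise_sd_log2,
    missing_rate = missing_rate, censor_mid = censor_mid,
    censor_scale = censor_scale,
    prob_symptomatic = prob_symptomatic, prob_male = prob_male,
    race_probs = race_probs,
    days_symptomatic = days_symptomatic,
    days_asymptomatic = days_asymptomatic, days_range = days_range,
    titer_slope = titer_slope, titer_intercept = titer_intercept,
    titer_noise_sd = titer_noise_sd,
    r2_days_titer = r2_days_titer, r2_tolerance = r2_tolerance,
    titer_min_dilution = titer_min_dilution,
    n_mod_peptides = as.integer(n_mod_peptides),
    n_shifted_peptides = as.integer(n_shifted_peptides),
    occupancy_shift = occupancy_shift,
    ptm_missing_rate = ptm_missing_rate,
    seed = as.integer(seed)
  )
  validate_cohort_design(design)
  structure(design, class = "cohort_design")
}

validate_cohort_design <- function(d) {
  stopifnot(
    d$n_pairs >= 1L, d$n_batches >= 1L, d$qc_interval >= 2L,
    d$n_proteins >= 1L,
    length(d$peptides_per_protein) == 2L, all(d$peptides_per_protein >= 1L),
    length(d$fragments_per_peptide) == 2L, all(d$fragments_per_peptide >= 1L),
    d$frac_differential >= 0, d$frac_differential <= 1,
    d$prob_up >= 0, d$prob_up <= 1,
    d$missing_rate >= 0, d$missing_rate <= 1,
    d$ptm_missing_rate >= 0, d$ptm_missing_rate <= 1,
    d$drift_amplitude >= 0, d$noise_sd_log2 >= 0,
    d$n_shifted_peptides <= d$n_mod_peptides
  )
  invisible(d)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Synthetic DIA serum cohort design\n")
  cat(sprintf("  %d matched pairs in %d batches, QC every %d subject runs\n",
              x$n_pairs, x$n_batches, x$qc_interval))
  cat(sprintf("  %d proteins (%.0f%% truly differential), drift %.2f log2 p-t\n",
              x$n_proteins, 100 * x$frac_differential, x$drift_amplitude))
  cat(sprintf("  %d hexose-modified peptides (%d with occupancy shift), seed %d\n",
              x$n_mod_peptides, x$n_shifted_peptides, x$seed))
  invisible(x)
}
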