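#' Generate run-level metadata for a synthetic cohort
#'
#' Lays out matched case/control pairs across acquisition batches, inserts
#' pooled QC injections (one opening each batch, one after every
#' `qc_interval` subject runs, one closing the batch), and draws the
#' demographics: pairs share age, sex, and race; convalescents additionally
#' carry symptom status, days since diagnosis, and antibody titer. Cases and
#' their matched controls are queued in succession, so the pair is measured
#' under near-identical instrument conditions.
#'
#' Symptomatic cases are drawn with longer days since diagnosis than
#' asymptomatic ones, and the latent log10 titer follows a linear trend in
#' days since diagnosis plus noise, calibrated so the squared correlation
#' between the two centers on the design target (`r2_days_titer`, default
#' 0.44). Latent titers below the assay's lowest dilution are reported as
#' "no antibody response" via the sentinel value `titer_min_dilution / 2`.
#'
#' @param design a [cohort_design()].
#' @return A data frame with one row per MS run: `run_id`, `subject_id`,
#'   `pair_id`, `cohort` (`control` / `convalescent` / `qc`), `batch`,
#'   `run_order` (acquisition index within batch), `age`, `sex`, `race`,
#'   `symptoms`, `days_since_diagnosis`, `titer`. QC rows carry no
#'   demographics. The titer sentinel is attached as attribute
#'   `titer_sentinel`.
#' @export
generate_metadata <- function(design) {
  validate_cohort_design(design)
  set.seed(design$seed)

  n <- design$n_pairs
  # pair-level demographics (shared by case and matched control)
  age <- round(stats::runif(n, 22, 61))
  sex <- ifelse(stats::runif(n) < design$prob_male, "male", "female")
  race <- sample(names(design$race_probs), n, replace = TRUE,
                 prob = design$race_probs)
  symptoms <- stats::runif(n) < design$prob_symptomatic
  days <- integer(n)
  days[symptoms] <- round(rtrunc_norm(sum(symptoms),
                                      design$days_symptomatic[1],
                                      design$days_symptomatic[2],
                                      design$days_range))
  days[!symptoms] <- round(rtrunc_norm(sum(!symptoms),
                                       design$days_asymptomatic[1],
                                       design$days_asymptomatic[2],
                                       design$days_range))
  latent_titer <- design$titer_intercept + design$titer_slope * days +
    stats::rnorm(n, 0, design$titer_noise_sd)
  sentinel <- design$titer_min_dilution / 2
  grid <- design$titer_min_dilution * 2^(0:11)
  titer <- vapply(latent_titer, function(lt) {
    if (lt < log10(design$titer_min_dilution)) return(sentinel)
    grid[which.min(abs(log10(grid) - lt))]
  }, numeric(1))

  # distribute pairs across batches, remainder to the earliest batches
  per_batch <- rep(n %/% design$n_batches, design$n_batches)
  extra <- n %% design$n_batches
  if (extra > 0L) per_batch[seq_len(extra)] <- per_batch[seq_len(extra)] + 1L
  pair_batch <- rep(seq_len(design$n_batches), per_batch)

  # randomize which member of the pair is injected first
  case_first <- stats::runif(n) < 0.5

  rows <- list()
  for (b in seq_len(design$n_batches)) {
    pairs_b <- which(pair_batch == b)
    run_order <- 0L
    n_subj <- 0L
    add <- function(row) rows[[length(rows) + 1L]] <<- row
    qc_row <- function() {
      run_order <<- run_order + 1L
      add(data.frame(run_id = sprintf("B%dR%02d", b, run_order),
                     subject_id = "QC", pair_id = NA_character_,
                     cohort = "qc", batch = b, run_order = run_order,
                     age = NA_real_, sex = NA_character_,
                     race = NA_character_, symptoms = NA,
                     days_since_diagnosis = NA_real_, titer = NA_real_))
    }
    subj_row <- function(i, is_case) {
      run_order <<- run_order + 1L
      n_subj <<- n_subj + 1L
      add(data.frame(
        run_id = sprintf("B%dR%02d", b, run_order),
        subject_id = sprintf("S%03d%s", i, if (is_case) "C" else "H"),
        pair_id = sprintf("PAIR%03d", i),
        cohort = if (is_case) "convalescent" else "control",
        batch = b, run_order = run_order,
        age = age[i], sex = sex[i], race = race[i],
        symptoms = if (is_case) symptoms[i] else NA,
        days_since_diagnosis = if (is_case) days[i] else NA_real_,
        titer = if (is_case) titer[i] else NA_real_))
    }
    qc_row()
    for (i in pairs_b) {
      for (is_case in if (case_first[i]) c(TRUE, FALSE) else c(FALSE, TRUE)) {
        if (n_subj > 0L && n_subj %% design$qc_interval == 0L) qc_row()
        subj_row(i, is_case)
      }
    }
    qc_row()
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  attr(md, "titer_sentinel") <- sentinel
  md
}

# Truncated normal draws by inverse-CDF on the truncated quantile range.
rtrunc_norm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Squared correlation between days since diagnosis and log10 titer
#'
#' Computed over convalescent runs, with the "no antibody response" sentinel
#' entering at its own log10 value (floor censoring rather than exclusion).
#' This is the quantity the generator calibrates to its design target.
#'
#' @param metadata output of [generate_metadata()].
#' @return Squared Pearson correlation (scalar).
#' @export
titer_days_r2 <- function(metadata) {
  cases <- metadata[metadata$cohort == "convalescent", ]
  stats::cor(cases$days_since_diagnosis, log10(cases$titer))^2
}

#' Case/control run pairing of a cohort
#'
#' @param metadata output of [generate_metadata()].
#' @return Data frame with one row per pair: `pair_id`, `case_run`,
#'   `control_run` (run ids of the convalescent and matched control).
#' @export
subject_pairs <- function(metadata) {
  subj <- metadata[metadata$cohort != "qc", ]
  ids <- unique(subj$pair_id)
  case <- control <- character(length(ids))
  for (k in seq_along(ids)) {
    rows <- subj[subj$pair_id == ids[k], ]
    if (nrow(rows) != 2L || length(unique(rows$cohort)) != 2L)
      stop("pair ", ids[k], " is not one case plus one control")
    case[k] <- rows$run_id[rows$cohort == "convalescent"]
    control[k] <- rows$run_id[rows$cohort == "control"]
  }
  data.frame(pair_id = ids, case_run = case, control_run = control)
}

#' Generate fragment-level intensities with known ground truth
#'
#' Builds a protein -> peptide -> fragment hierarchy and simulates log2
#' fragment intensities as protein baseline + peptide offset + fragment
#' offset + subject biological variation + cohort effect (differential
#' proteins, convalescent runs only) + batch offset + smooth run-order drift
#' (one low-order polynomial curve per batch, scaled per fragment by a
#' sensitivity multiplier) + measurement noise. QC runs share a single
#' latent pooled profile, so their only variation is drift plus noise.
#' Values are removed by baseline missingness plus logistic low-intensity
#' censoring, then returned on the linear scale.
#'
#' @param design a [cohort_design()].
#' @param metadata output of [generate_metadata()] for the same design.
#' @return A list of class `fragment_table`:
#'   `intensity` (fragments x runs linear-scale matrix, `NA` = missing),
#'   `fragments` (data frame: `fragment_id`, `peptide`, `protein`),
#'   and `truth` (list with per-protein `effects` in log10 units, the
#'   race-coupling table, per-batch `drift` curves at each run position,
#'   and the per-fragment drift `sensitivity`).
#' @export
generate_fragments <- function(design, metadata) {
  validate_cohort_design(design)
  force(metadata)
  set.seed(design$seed + 1L)

  n_pep <- sample_range(design$n_proteins, design$peptides_per_protein)
  protein <- rep(sprintf("P%03d", seq_len(design$n_proteins)), n_pep)
  peptide <- sprintf("%s_pep%02d", protein,
                     unlist(lapply(n_pep, seq_len), use.names = FALSE))
  n_frag <- sample_range(length(peptide), design$fragments_per_peptide)
  frag_pep <- rep(peptide, n_frag)
  frag_prot <- rep(protein, n_frag)
  fragment_id <- sprintf("%s_f%d", frag_pep,
                         unlist(lapply(n_frag, seq_len), use.names = FALSE))
  n_f <- length(fragment_id)

  # true differential effects (log10, convalescent - control)
  effects <- numeric(design$n_proteins)
  names(effects) <- sprintf("P%03d", seq_len(design$n_proteins))
  n_diff <- round(design$frac_differential * design$n_proteins)
  diff_idx <- if (n_diff > 0L) sample.int(design$n_proteins, n_diff) else integer(0)
  if (n_diff > 0L) {
    mag <- pmax(stats::rnorm(n_diff, design$effect_mean_log10,
                             design$effect_sd_log10), 0.02)
    sign <- ifelse(stats::runif(n_diff) < design$prob_up, 1, -1)
    effects[diff_idx] <- sign * mag
  }
  # race-coupled subset: effect amplified in black, damped otherwise
  n_rc <- min(design$n_race_coupled, n_diff)
  race_coupled <- if (n_rc > 0L) sample(names(effects)[diff_idx], n_rc) else character(0)
  race_gain <- c(black = 1.8, other = 0.4)

  # per-batch smooth drift curves over run positions (log2)
  batches <- sort(unique(metadata$batch))
  drift <- lapply(batches, function(b) {
    t <- metadata$run_order[metadata$batch == b]
    ts <- 2 * (t - min(t)) / max(1, diff(range(t))) - 1
    co <- stats::rnorm(3)
    raw <- co[1] * ts + co[2] * ts^2 + co[3] * ts^3
    span <- diff(range(raw))
    val <- if (span > 0 && design$drift_amplitude > 0)
      (raw - mean(raw)) * design$drift_amplitude / span else rep(0, length(raw))
    stats::setNames(val, metadata$run_id[metadata$batch == b])
  })
  names(drift) <- paste0("batch", batches)
  drift_by_run <- unlist(unname(drift))[metadata$run_id]
  batch_offset <- stats::rnorm(length(batches), 0, design$batch_sd_log2)

  sens <- stats::runif(n_f, 0.6, 1.4)
  # baselines floored so every protein stays quantifiable after the
  # missingness filter (the design emulates a post-filter protein count)
  base <- pmax(stats::rnorm(design$n_proteins, 17, 2), 14)[match(frag_prot, names(effects))] +
    stats::rnorm(length(peptide), 0, 1)[match(frag_pep, peptide)] +
    stats::rnorm(n_f, 0, 0.8)

  # subject biological variation acts at the protein level: one draw per
  # subject x protein, shared by all fragments of the protein
  subj <- metadata$subject_id[metadata$cohort != "qc"]
  prot_idx <- match(frag_prot, names(effects))
  bio_prot <- matrix(stats::rnorm(design$n_proteins * length(subj), 0,
                                  design$subject_sd_log2),
                     nrow = design$n_proteins,
                     dimnames = list(names(effects), subj))
  effect_log2 <- effects * log2(10)

  n_runs <- nrow(metadata)
  log2i <- matrix(base, n_f, n_runs)
  colnames(log2i) <- metadata$run_id
  for (j in seq_len(n_runs)) {
    md <- metadata[j, ]
    col <- log2i[, j] + batch_offset[match(md$batch, batches)] +
      sens * drift_by_run[j]
    if (md$cohort != "qc") {
      col <- col + bio_prot[prot_idx, md$subject_id]
      if (md$cohort == "convalescent") {
        eff <- effect_log2[prot_idx]
        rc <- frag_prot %in% race_coupled
        if (any(rc)) {
          gain <- if (identical(md$race, "black")) race_gain[["black"]] else race_gain[["other"]]
          eff[rc] <- eff[rc] * gain
        }
        col <- col + eff
      }
    }
    log2i[, j] <- col
  }
  log2i <- log2i + stats::rnorm(n_f * n_runs, 0, design$noise_sd_log2)

  # missingness: baseline + logistic low-intensity censoring
  p_censor <- stats::plogis((design$censor_mid - log2i) / design$censor_scale)
  p_miss <- 1 - (1 - design$missing_rate) * (1 - p_censor)
  miss <- matrix(stats::runif(n_f * n_runs), n_f, n_runs) < p_miss
  intensity <- 2^log2i
  intensity[miss] <- NA_real_
  rownames(intensity) <- fragment_id

  structure(list(
    intensity = intensity,
    fragments = data.frame(fragment_id = fragment_id, peptide = frag_pep,
                           protein = frag_prot),
    truth = list(
      effects = effects,
      race_coupled = race_coupled,
      race_gain = race_gain,
      drift = drift,
      sensitivity = stats::setNames(sens, fragment_id),
      batch_offset = stats::setNames(batch_offset, paste0("batch", batches))
    )
  ), class = "fragment_table")
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate paired modified/unmodified peptide intensities
#'
#' Simulates hexose-modified peptide channels: each peptide has a baseline
#' modification occupancy, and for a configured subset the occupancy is
#' shifted (on the logit scale) in convalescent runs. Modified and
#' unmodified intensities split a common log-normal total per run.
#'
#' @param design a [cohort_design()].
#' @param metadata output of [generate_metadata()].
#' @return A list of class `ptm_table`: `table` (long data frame with
#'   `peptide`, `run_id`, `modified_intensity`, `unmodified_intensity`) and
#'   `truth` (per-peptide logit occupancy shift; 0 for unshifted peptides).
#' @export
generate_ptm_table <- function(design, metadata) {
  validate_cohort_design(design)
  force(metadata)
  set.seed(design$seed + 2L)
  subj <- metadata[metadata$cohort != "qc", ]
  n_p <- design$n_mod_peptides
  peptides <- sprintf("MODPEP%03d", seq_len(n_p))
  base_occ <- stats::qlogis(stats::runif(n_p, 0.05, 0.5))
  shift <- stats::setNames(rep(0, n_p), peptides)
  if (design$n_shifted_peptides > 0L)
    shift[sample.int(n_p, design$n_shifted_peptides)] <- design$occupancy_shift

  rows <- vector("list", n_p)
  for (k in seq_len(n_p)) {
    total_log2 <- stats::rnorm(1, 16, 1.5) +
      stats::rnorm(nrow(subj), 0, 0.5)
    occ_logit <- base_occ[k] +
      ifelse(subj$cohort == "convalescent", shift[k], 0) +
      stats::rnorm(nrow(subj), 0, 0.3)
    occ <- stats::plogis(occ_logit)
    mod <- 2^total_log2 * occ *
      2^stats::rnorm(nrow(subj), 0, design$noise_sd_log2)
    unmod <- 2^total_log2 * (1 - occ) *
      2^stats::rnorm(nrow(subj), 0, design$noise_sd_log2)
    mod[stats::runif(nrow(subj)) < design$ptm_missing_rate] <- NA_real_
    unmod[stats::runif(nrow(subj)) < design$ptm_missing_rate] <- NA_real_
    rows[[k]] <- data.frame(peptide = peptides[k], run_id = subj$run_id,
                            modified_intensity = mod,
                            unmodified_intensity = unmod)
  }
  structure(list(table = do.call(rbind, rows), truth = list(shift = shift)),
            class = "ptm_table")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper returning metadata, fragment table (with truth), and
#' the PTM table for one design.
#'
#' @param design a [cohort_design()].
#' @return List with elements `design`, `metadata`, `fragments`, `ptm`.
#' @export
simulate_cohort <- function(design = cohort_design()) {
  metadata <- generate_metadata(design)
  fragments <- generate_fragments(design, metadata)
  ptm <- generate_ptm_table(design, metadata)
  list(design = design, metadata = metadata, fragments = fragments, ptm = ptm)
}
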