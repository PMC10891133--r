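---
title: "Methods: DIA serum cohort analysis in diaserum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIA serum cohort analysis in diaserum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaserum)
```

# The analysis

`diaserum` implements a complete case-control serum proteomics analysis for
data-independent acquisition (DIA) mass spectrometry, organized around a
matched-pair design: convalescent cases are matched one-to-one to healthy
controls on age, sex, and race, pairs are acquired in succession within
acquisition batches, and an identical pooled quality-control (QC) digest is
injected at regular intervals to expose purely technical variation. The
chain is:

1. **Fragment filtering.** Fragment ions missing in more than half of all
   runs (subjects and QC alike) are removed; exactly half is retained.
2. **Drift correction.** On the log2 scale, each fragment's within-batch
   time trend over run order is estimated by Nadaraya–Watson regression
   with a Gaussian kernel of standard deviation 5 runs and subtracted,
   restoring the fragment's batch mean so correction removes trend, not
   level.
3. **Median equalization.** Each batch is shifted additively (log2) so its
   median equals the grand median of batch medians, then intensities
   return to the linear scale.
4. **Rollup.** Per protein, fragments are ranked by the Pearson
   correlation of their log2 profile with the protein's median fragment
   profile; the top 5 are summed on the linear scale per run and
   log10-transformed. Proteins with fewer than 2 fragments keep what they
   have and are flagged.
5. **QC reliability.** Per protein and batch, the coefficient of variation
   (CoV, percent, sample SD over mean of linear QC levels) is averaged
   over batches; proteins with average CoV strictly above 50% carry an
   "unreliable" flag into every downstream table.
6. **Paired differential testing.** Two-tailed paired t-test on log10
   levels per protein (pairwise-complete pairs, at least 3), BH-adjusted
   in a single family; tiers at adjusted p < 0.05 (primary) and < 0.20
   (extended); the directed value ±(1 − p_adj), signed by the fold
   change, feeds ranking and display.
7. **Covariate models.** Six OLS families — univariate and multivariate
   over Age, Sex, Race, Symptoms, Days since diagnosis — on control
   levels, case levels, and paired log10 ratios (the ratio multivariate
   model adds Age×Sex). Titer is excluded from modeling because it is
   collinear with symptoms and days since diagnosis. BH is applied within
   each (dataset, form, term) family across proteins.
8. **Profile clustering.** Median-centered protein signatures,
   complete-linkage agglomeration on `1 − Pearson` distance
   (pairwise-complete), cut into 20 flat clusters.
9. **PTM occupancy.** For hexose-modified peptides the modification level
   is `log2(mod / (mod + unmod))`; peptides with more than 20% missing
   levels across subject runs are dropped; cohorts are compared by the
   same paired test with BH adjustment.
10. **Enrichment map.** Proteins ranked by directed adjusted p, classic
    preranked enrichment (weighted Kolmogorov–Smirnov running sum, weight
    exponent 1, 1000 membership permutations, same-sign permutation p,
    pooled-null FDR q), gene sets restricted to 3–300 members in the
    universe; the map keeps nodes at q < 0.01 and joins sets whose
    Jaccard index is at least 0.80.

# Key parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `kernel_sd` | 5 | runs | Kernel standard deviation of the drift smoother. The width is stated as an SD equivalent to 5 samples; we treat the SD reading as the precise one and use full support (no truncation). |
| `max_fragments` / `min_fragments` | 5 / 2 | fragments | Rollup selection. The original rollup delegates selection to an external tool without published parameters; this correlation-ranked top-k rule is a transparent equivalent with k exposed. |
| `cov_threshold` | 50 | % CoV | Reliability flag; strictly-greater comparison, so 50.0 is reliable. |
| `alpha` / `alpha_extended` | 0.05 / 0.20 | adjusted p | Primary and extended significance tiers. |
| `min_pairs` | 3 | pairs | Minimum complete pairs per protein/peptide for the paired test. |
| `k_clusters` | 20 | clusters | Flat cut of the profile dendrogram, chosen for a ~330-protein panel. |
| `n_perm` | 1000 | permutations | Preranked enrichment null. |
| `min_set_size` / `max_set_size` | 3 / 300 | members | Gene-set size bounds after universe intersection. |
| `fdr_cutoff` / `jaccard_min` | 0.01 / 0.80 | q / index | Node retention and edge criterion of the enrichment map. Reports of comparable maps mix 0.05 and 0.01 cutoffs; both are accepted, 0.01 is the default. |
| `ptm_max_missing` | 0.20 | fraction | Missingness filter on modification levels, counted over the 58 subject runs (not QC runs — QC carries no occupancy contrast). |

# The synthetic cohort generator

Every stage is exercised on `cohort_design()` cohorts with known ground
truth. The defaults encode the emulated study conditions: 29 matched pairs
in 4 batches, a pooled QC injection opening and closing each batch and
after every 6 subject runs (74 runs total), 334 proteins in a
protein→peptide→fragment hierarchy (1–3 peptides of 2–4 fragments), 37
truly differential proteins (22 elevated, 15 lowered; log10 magnitudes
N(0.2, 0.05)), six of them race-modulated, and 55 hexose-modified peptide
channels with 3 occupancy-shifted peptides.

Log2 fragment intensity is additive: protein baseline N(17, 2) (floored at
14 so the default design yields exactly 334 quantifiable proteins after
filtering — the emulated protein count is itself a post-filter quantity)
+ peptide and fragment offsets + subject×protein biological variation
(SD 0.5 log2) + cohort effect on convalescent runs + batch offset (SD 0.3
log2) + drift + noise (SD 0.3 log2). Drift is one smooth random cubic per
batch, scaled to a 0.8 log2 peak-to-trough amplitude and modulated per
fragment by a sensitivity multiplier in [0.6, 1.4] — a shape a kernel
smoother on run order can capture, which is the point of the emulation.
QC runs share a single latent pooled profile, so their only within-batch
variation is drift plus noise. Missingness is a 3% baseline plus logistic
low-intensity censoring (midpoint log2 = 11), making missingness
intensity-biased as in real DIA data.

Demographics: pairs share age (uniform 22–61), sex (P(male) ≈ 0.55) and
race (45% white, 45% black, 5% asian, 5% other); cases are symptomatic
with probability 15/29. Days since diagnosis are truncated normal, mean 59
(SD 11) for symptomatic and 32 (SD 6) for asymptomatic cases on a 9–70 day
range. Latent log10 titer is `0.41 + 0.04·days + N(0, 0.62)`, snapped to a
doubling dilution grid starting at 1:50; latent titers below the lowest
dilution become a "no antibody response" sentinel strictly below it. The
noise SD was chosen so the squared days–titer correlation (computed with
the sentinel entering at its own log10 value) centers on the 0.44 design
target; the generator declares a ±0.25 band for a single 29-pair cohort,
the sampling spread of r² at that n.

**What the generator does not emulate:** retention-time or m/z structure,
peptide-level interference, shared peptides between proteins (lineage is
unambiguous), correlated missingness across fragments of a run, batch
differences in missingness, or longitudinal sampling. Passing tests
therefore demonstrate that the statistical machinery recovers truth under
an additive log-normal model with smooth drift — not that any biological
conclusion transfers to a particular measured cohort.

# Numerical choices and degenerate inputs

- Nonpositive intensities are treated as missing before any log: a zero
  in a DIA export is an absence call, not a measurement.
- Drift trends for fragments with fewer than two observations in a batch
  fall back to the batch mean; correction centers on the trend mean over
  the fragment's observed runs, so the observed within-batch mean is
  exactly preserved.
- Zero-variance paired differences would give p = 0; instead p is floored
  at the smallest representable double and the protein flagged, keeping
  −log10 p finite downstream.
- A fold change of exactly 0 gets directed value 0 (the two-branch sign
  rule leaves ties undefined).
- Pearson distances with fewer than 3 shared observations or zero
  variance are set to the maximal value 2, so degenerate profiles remain
  placeable; rows with fewer than 3 observed values are dropped and
  logged before clustering.
- Modification level with modified intensity 0 is missing rather than
  −∞: indistinguishable from a detection failure.
- Ordination axis signs are fixed by forcing each component's
  largest-magnitude loading positive.
- Enrichment ties are broken by protein identifier so permutation nulls
  are bit-reproducible under a fixed seed; the q of a set is the best
  achievable pooled-null FDR among same-sign cutoffs that retain it, so q
  never increases with |NES|.

# Design choices where the design was open

- **Median equalization uses all runs, QC included.** Whether the
  original equalization used subject runs only is unknowable from the
  text; including QC is symmetric and keeps QC runs comparable across
  batches. Flagged as a choice, not a claim.
- **QC runs participate in drift fitting** — they are interleaved
  precisely to capture drift.
- **Pairing under missingness** is pairwise-complete per protein with a
  3-pair minimum; the alternative (dropping proteins with any incomplete
  pair) discards most of the panel at realistic missingness.
- **BH family structure**: one family for the overall comparison (one
  volcano); within (dataset, form, term) across proteins for the model
  grid, mirroring per-comparison report columns.
- **Race encoding**: indicator contrasts against the most frequent level,
  all levels retained (display conventions that subset to two races do
  not constrain the model).
- **PTM missingness is counted over the 58 subject runs**, since QC runs
  contribute no case/control contrast.
- **Cluster function annotation** is a local hypergeometric
  over-representation test against user-supplied sets, replacing
  web-service enrichment.

# Problem sizes in the test suite

The suite verifies oracle agreement on enumerated small instances
(kernel regression, BH, t-test, Jaccard, modification level, median
centering, exhaustive complete-linkage on ≤ 8 rows), and runs the
full default design where the claim concerns the study scale: drift
reduction of QC CoV over 10 seeds, false-discovery control on 50 null
cohorts of 334 proteins × 29 pairs, recovery of 0.2 log10 effects over 3
seeds, enrichment sanity over 3 planted rankings and 20 null-ranking
repeats (200–500 permutations each). These sizes make the whole suite run
in a few minutes while keeping every assertion at the design's stated
scale.

# Limitations

- The fragment-selection and rollup rule is a documented transparent
  stand-in for an external tool whose exact criteria are unpublished;
  protein levels from the two will differ in detail.
- The paired t-test uses no variance moderation; with 29 pairs this is
  deliberate (no shrinkage target is available for a 334-protein serum
  panel without further assumptions).
- PLS-DA is used descriptively (two components, cohort response); no
  cross-validated error is reported.
- The CoV scale (linear, sample SD) is the conventional choice; counts of
  flagged proteins are sensitive to it.

# A worked mini-example

```{r example, eval = FALSE}
co <- simulate_cohort(cohort_design(seed = 1))
pm <- normalize_cohort(co$fragments, co$metadata)
diff <- paired_differential(pm$protein, co$metadata)
table(diff$tier)
```

The `analysis/` directory holds the end-to-end numbered drivers
(`01_simulate.R` … `08_enrichment_map.R`) that chain these stages on one
synthetic cohort and write every stage table under `results/`.
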