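Package: diaserum
Title: DIA Serum Proteomics Cohort Analysis with Run-Order Drift Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for case-control serum proteomics cohorts
    measured by data-independent acquisition (DIA) mass spectrometry, built
    around a matched-pair COVID-19 convalescent study design. Implements
    fragment-level preprocessing (missingness filtering, per-batch Gaussian
    kernel drift correction on run order, cross-batch median equalization),
    correlation-ranked fragment selection and protein rollup, reliability
    assessment from interleaved pooled quality-control runs, paired
    differential abundance testing with Benjamini-Hochberg control and the
    directed (1 - adjusted p) ranking transform, demographic covariate
    regression, complete-linkage profile clustering on correlation distance,
    hexose-modification occupancy analysis, and preranked set enrichment with
    a Jaccard-linked enrichment map. A synthetic cohort generator with known
    ground truth emulates the full study design (matched pairs, batches,
    interleaved QC runs, acquisition drift, intensity-dependent missingness)
    so every stage is testable end to end without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    cluster,
    withr
Config/testthat/edition: 3
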