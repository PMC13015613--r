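Package: methylcimt
Title: Epigenome-Wide Association and Causal Triangulation for Carotid
    Intima-Media Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for blood DNA-methylation studies of carotid
    intima-media thickness (cIMT) and related vascular phenotypes. Provides
    beta-value computation and marker/sample quality control with quantile
    normalisation; per-stratum linear-model epigenome-wide association of
    CpG methylation with log cIMT; sample-size weighted Stouffer and
    inverse-variance fixed-effects meta-analysis with Cochran's Q and I2
    heterogeneity and a two-stage discovery design with subset Bonferroni
    correction; cis-window meQTL/eQTL/eQTM mapping; single-instrument
    Wald-ratio summary-data Mendelian randomisation and Bayesian
    colocalisation with prior sensitivity analysis; methylation-matched
    permutation enrichment for gene sets and transcription-factor binding
    sites; and a weighted methylation risk score evaluated against age-,
    sex- and ethnicity-specific normative cIMT thresholds. A synthetic-data
    module generates multi-ethnic cohorts, regional summary statistics and
    annotation fixtures with known planted truth so that every stage is
    testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    pROC,
    fgsea,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
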