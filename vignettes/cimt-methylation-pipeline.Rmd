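---
title: "Methods: an EWAS-to-risk-score pipeline for carotid intima-media thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EWAS-to-risk-score pipeline for carotid intima-media thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcimt)
```

# Scope and model

`methylcimt` implements a complete analytical workflow for blood
DNA-methylation studies of carotid intima-media thickness (cIMT), a
subclinical ultrasound measure of atherosclerosis. The pipeline covers
eight stages, each a small module with a tested surface:

1. **Synthetic data** (`synth_config()`, `generate_methylation_cohort()`,
   `generate_region_sumstats()`, `generate_normative_table()`,
   `generate_annotation_fixtures()`): inputs with known planted truth.
2. **Methylation preparation** (`beta_from_intensities()`,
   `filter_markers()`, `exclude_samples()`, `quantile_normalize()`).
3. **EWAS** (`fit_cpg_association()`, `run_stratified_ewas()`): per-stratum
   OLS of `ln(cIMT)` on each CpG beta value plus covariates.
4. **Meta-analysis** (`stouffer_combine()`, `ivw_combine()`,
   `heterogeneity()`, `two_stage_meta()`, `bonferroni_threshold()`,
   `concordance_diagnostics()`, `discovery_specific_rate()`).
5. **cis-QTL mapping** (`enumerate_cis_pairs()`, `fit_qtl()`, `meta_qtl()`,
   `run_cis_scan()`): meQTL, eQTL and eQTM scans sharing the EWAS engine.
6. **Causal triangulation** (`select_instrument()`, `smr_wald()`,
   `coloc_abf()`, `p12_sensitivity()`, `classify_evidence()`).
7. **Matched-background enrichment** (`match_spec()`, `cpg_summary()`,
   `match_background()`, `overlap_enrichment()`, `run_enrichment()`).
8. **Methylation risk score** (`derive_weights()`, `compute_mrs()`,
   `classify_elevated()`, `stratified_split()`, `evaluate_roc()`,
   `quartile_association()`).

The statistical model of the association stage is

$$\ln(\text{cIMT}_i) = \alpha + \beta\, m_{ij} + \boldsymbol\gamma' \mathbf{c}_i + \varepsilon_i$$

fitted independently per CpG $j$ and per ethnic stratum, where $m_{ij}$ is
the methylation beta value ($M/(M+U+100)$, in $[0,1)$) and
$\mathbf{c}_i$ the covariates (age, sex, smoking, cell-type proportions,
technical principal components). Strata can be as small as ~150
participants, so two-sided P-values come from the $t$ reference on the
residual degrees of freedom, not the normal.

Per-stratum statistics are combined by the sample-size weighted Stouffer
method,

$$Z_{\text{meta}} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}},\qquad w_i = \sqrt{n_i},$$

the convention of the METAL software. Stouffer rather than
inverse-variance weighting is the discovery workhorse because external
cohorts frequently differ in measurement protocol and model specification,
so effect sizes are not on a common scale; `ivw_combine()` and
`concordance_diagnostics()` exist to quantify how much the two methods
agree on any given data set, and `heterogeneity()` supplies Cochran's
$Q$ and $I^2 = \max(0, (Q-(k-1))/Q)\times 100$.

The two-stage design (`two_stage_meta()`) mirrors a discovery/validation
split: stage 1 combines the discovery strata and carries forward probes
with $p < \alpha_1$ (default 0.05); stage 2 re-combines discovery plus
additional studies at the carried-forward probes present in **all**
contributing datasets (a 450K-array study therefore restricts the family
to 450K/EPIC-overlapping sites; the availability fraction is reported),
and declares sentinels at the subset Bonferroni threshold
$\alpha_2 / (\text{number of stage-2 tests})$ — the family is the set of
probes actually meta-analysed in stage 2, not the array total. Per-probe
study subsets (rather than the complete-study requirement) are available
via `complete_studies = FALSE`.

# Causal triangulation

Instruments are cis-meQTL variants with $p < 10^{-5}$ and
$F = (\hat\beta/\text{se})^2 \ge 10$; ties on P are broken by larger $F$,
then lexicographic variant id, so selection is reproducible. The
summary-data Mendelian randomisation estimate is the Wald ratio
$\hat\beta_{\text{SMR}} = \hat\beta_{\text{out}}/\hat\beta_{\text{exp}}$,
tested with

$$T = \frac{z_{\text{exp}}^2 z_{\text{out}}^2}{z_{\text{exp}}^2 + z_{\text{out}}^2} \sim \chi^2_1,$$

the standard single-instrument SMR test; the standard error is
back-derived as $|\hat\beta_{\text{SMR}}|/\sqrt{T}$. With a single
instrument, pleiotropy-robust multi-instrument estimators are out of
scope by design.

`coloc_abf()` evaluates the five single-causal-variant hypotheses
H0–H4 from per-variant Wakefield approximate Bayes factors with prior
effect SD 0.15 for quantitative traits and 0.2 for case-control traits
(the de-facto defaults of the approximate-Bayes-factor colocalisation
literature; the inputs here do not identify these scales, so they are
fixed constants). Priors default to $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$. All hypothesis sums are accumulated in log space, so
posteriors remain normalised even at $|z| > 30$. `p12_sensitivity()`
re-evaluates the posterior over a user-configurable $p_{12}$ grid and
reports the robustness window where $PP_{H4} > 0.5$ and
$PP_{H4}/PP_{H3} \ge 3$; the grid is configurable because sensible bounds
are data-dependent. `classify_evidence()` encodes the decision rule:
*supported_shared* iff $p_{\text{SMR}} < 0.05$ and $PP_{H4} > 0.5$;
*flagged_H3* iff $p_{\text{SMR}} < 0.05$ and $PP_{H3} > 0.5$ (possible
shared regulation diluted by LD differences or multiple causal variants);
otherwise *none*. The rule is monotone in $PP_{H4}$.

# Matched-background enrichment

Methylation arrays oversample CpGs near well-annotated genes, so naive
enrichment of association hits is biased. `match_background()` builds,
for every test CpG, 200 background CpGs matched on mean and SD of
methylation, drawn from candidates more than 5 kb from **every** test CpG
(a per-test-CpG-only distance variant would be weaker; the global rule is
the default). Tolerances expand in lockstep over 10 evenly spaced steps,
mean from ±0.025 to ±0.25 and SD from ±0.0025 to ±0.025, stopping at the
first step with at least 200 candidates; the candidates are then sampled
without replacement (seeded) rather than taken nearest-first, which would
systematically favour the closest-matched probes. A CpG unmatched at the
widest tolerance is an error, not a silent omission. Background CpGs may
recur across different test CpGs within one set, but never within one
test CpG.

The empirical P of a term is the fraction of background sets whose
overlap **equals or exceeds** the test overlap — ties count against the
test set — and significance is $p < 0.005$, i.e. zero qualifying sets out
of 200. Gene-set mode maps CpGs to genes through a cis-eQTM table
restricted to supported pairs ($p < 0.05$) and counts distinct genes;
TFBS mode counts CpGs falling inside BED intervals, which are treated as
0-based half-open throughout (1-based CpG position $x$ overlaps
$[s, e)$ iff $s \le x - 1 < e$).

# Methylation risk score

$\text{MRS} = \sum_i w_i b_i$ over the sentinel CpGs, where $w_i$ is the
Stouffer combination across ethnicities of the per-ethnicity association
z (from `ln(cIMT) ~ CpG + age + sex` by default — the *basic* model; a
*comprehensive* variant re-derives weights under the full EWAS covariate
set), and $b_i$ is the per-CpG rank-based inverse-normal transform of
beta across the scored samples. "Quantile-normalised beta" admits two
readings; the rank-based transform was chosen because it makes scores
invariant to any per-CpG monotone transformation of the raw values and
is insensitive to outliers; weights are used raw (any common scaling
cancels in ROC and quartile analyses).

Elevated cIMT is cIMT **at or above** the age-, sex- and
ethnicity-specific 75th percentile of a normative table (`strict = TRUE`
switches to strictly-above); ages beyond the table's last band (80 years)
raise an error so unsupported participants are excluded upstream, never
silently classified. The 70/30 split is stratified on ethnicity × elevated
status with largest-remainder rounding, so per-cell balance differs by at
most one sample. Evaluation fits nested logistic models on the training
set and scores the held-out set: M1 = MRS + age + sex + ethnicity, M2 =
age + sex + ethnicity, and M3 = M2 + smoking — since "M2 + smoking" could
either include or exclude the MRS, both variants are emitted, labelled
`m3_smoking` and `m3_smoking_mrs`. AUCs use the rank statistic with ties
counted half; CIs and the paired M1-vs-M2 difference use DeLong's
structural-components covariance estimator (via pROC). Quartiles are
type-7 quantiles of the scored (test) distribution — test-set rather than
training-set cut-points, since the quartile analysis describes the
evaluated cohort — with ties assigned to the lower quartile; effect
modification by ethnicity is a likelihood-ratio test of the
quartile×ethnicity interaction against $\chi^2$ on the added degrees of
freedom.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is verified.

* **Cohort structure.** Named ethnic strata of configurable size (default
  1000/150/150, a large stratum plus two small ones); age uniform on
  30–80 years; sex, smoking (never/former/current at 60/25/15%),
  Dirichlet leukocyte proportions dominated by granulocytes, and standard
  normal technical PCs.
* **Methylation.** Beta values are logit-normal: per-CpG mean logit
  $\mu_j \sim N(0, 1.5^2)$ (bimodal beta distribution, mass near 0 and 1,
  as on arrays) with between-sample SD 0.4 on the logit scale, keeping
  strict $(0,1)$ support without boundary mass. Causal CpGs draw
  $\mu_j \sim N(0, 0.5^2)$ — the variable, intermediate-methylation part
  of the array — because a CpG with no between-sample variability cannot
  carry an association signal.
* **Outcome.** $\ln(\text{cIMT})$ is linear in age, sex, smoking and the
  planted CpG effects (betas centred at 0.5) with Gaussian noise
  (default residual SD 0.1, i.e. ~10% coefficient of variation around a
  ~0.55–0.9 mm range), so cIMT is log-normal and the EWAS log transform
  is exactly the model scale. The default planted effect is 0.5 per
  beta-unit: with typical causal-CpG variability this is comfortably
  detectable at n = 1300 but invisible per stratum at genome-wide
  thresholds, exercising the two-stage logic. Strata share causal CpGs;
  per-stratum effect multipliers can inject heterogeneity for $I^2$
  tests.
* **Regional summary statistics.** Haplotypes are thresholded latent
  Gaussian AR(1) series (adjacent correlation 0.8), giving regional LD
  that decays geometrically — the simplest structure with realistic
  association decay. Scenarios: *shared* (one variant drives both traits;
  the outcome effect is `mediation_slope × region_effect`, so the Wald
  ratio targets `mediation_slope`, default 0.5), *distinct* (two variants
  at the 1st and 3rd quartile positions of the region, essentially
  unlinked), and *null*. Defaults (40 SNPs, exposure/outcome n = 5000,
  per-allele effect 0.3 SD) give instrument-grade exposure signals,
  matching the well-powered QTL resources the causal stage assumes.
* **Normative table.** A multiplicative log-scale model of the 75th
  percentile over age bands × sex × ethnicity, monotone in age by
  construction; `calibrate_normative_params()` fits the parameters from a
  reference cohort so synthetic prevalence of elevated cIMT lands near
  25%.
* **Annotation fixtures.** A GMT collection with one term covering the
  genes cis-mapped to the causal CpGs, a BED track covering the causal
  CpG positions, and an eQTM map with strong support at planted pairs and
  uniform-P noise elsewhere.

What the generator does **not** emulate: probe-level technical artefacts
(IDAT intensities, detection P, batch effects), genome-wide LD maps,
population stratification confounding, and real covariate-methylation
correlation structure (cell proportions are independent of the outcome).
Passing tests therefore demonstrate correctness of the statistical
machinery under the assumed model, not robustness to the full messiness
of real cohort data.

# Numerical and degenerate-input choices

* Quantile normalisation maps each sample onto the cross-sample mean
  order statistics, interpolating over non-missing entries per sample
  (via `limma::normalizeQuantiles`, ties averaged); a single sample is
  returned unchanged with a warning.
* Constant covariates (e.g. smoking in a tiny stratum) are dropped per
  stratum with a logged note; genuinely collinear designs raise an error
  naming the offending columns. An exact-fit regression (zero residual
  variance) is flagged `degenerate` rather than reporting an infinite z
  silently.
* Sample-exclusion reasons follow the fixed precedence
  sex_mismatch > duplicate > scan_fail so QC logs are reproducible;
  reason counts are non-exclusive (a probe or sample may fail several
  checks) alongside the count actually removed.
* The cis window is **inclusive** at exactly 1 Mb (a partner at
  1,000,000 bp is in; 1,000,001 is out), and gene anchors are the
  manifest-supplied transcription start sites.
* Probes with a zero z in either analysis are excluded from the sign
  concordance denominator.
* Stouffer uses the $\sqrt{\sum w_i^2}$ denominator; missing studies are
  dropped per probe, and a probe missing in every study is omitted with
  `k = 0`.
* All coloc hypothesis sums use log-sum-exp; $PP_{H3}$ uses a guarded
  log-difference that degrades to $-\infty$ (never a negative
  probability) when the two-term difference underflows.

# Problem sizes in the test suite

The packaged tests verify calibration and recovery at sizes chosen to
give stable verdicts at interactive runtimes: Stouffer type-I error over
50,000 null probes × 3 strata; IVW against a weighted-least-squares
oracle on 1,000 random problems; colocalisation against exhaustive
configuration enumeration on ≤ 6-variant regions plus 100 seeds per
regional scenario; Wald-ratio recovery over 500 seeds (n = 2000, 30
SNPs); the background matcher against a brute-force schedule scan on
5,000-CpG universes; and 20 full pipeline replicates at 20,000 CpGs with
strata 1000/150/150. `scripts/acceptance.R` re-runs the same analyses at
modestly reduced replicate counts and writes the headline quantities as
JSON.

# Interface

The package is library-first, in the style of the established omics
analysis packages: the exported functions compose the pipeline, and this
vignette plus the README's worked example are the interface; no shell
entry points are shipped. Tab-delimited readers/writers (`read_assoc()`,
`read_sumstats()`, `read_gmt()`, `read_bed()`, `write_cohort_bundle()`
and their counterparts) define the interchange formats between stages so
each stage can also be driven from files produced elsewhere.

# Known limitations

* Single-instrument SMR cannot separate causality from pleiotropy at the
  instrument; the colocalisation posterior is the only triangulating
  evidence.
* The colocalisation model assumes at most one causal variant per trait
  per region; multiple causal variants inflate $PP_{H3}$, which is why
  *flagged_H3* is reported rather than discarded.
* The enrichment empirical P has resolution 1/200; significance at
  $p < 0.005$ is exactly "zero background sets at or above the test
  overlap" and cannot be made more granular without more sets.
* Houseman cell-type deconvolution, expression latent-factor estimation
  and genetic-ancestry PCs are consumed as supplied covariates, never
  estimated internally.
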