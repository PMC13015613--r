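#' Configuration for the synthetic cohort and region generators
#'
#' Collects every tunable of the synthetic-data module in one validated
#' object.  Defaults emulate the study conditions of a multi-ethnic Asian
#' EWAS of cIMT: three ethnic strata of unequal size, a large null CpG
#' background with a handful of causal CpGs acting on log cIMT, and
#' cis-regulated regions with shared-variant, distinct-variant and null
#' genetic architectures.
#'
#' @param seed integer seed; the generators are fully deterministic given
#'   the config (identical config => byte-identical output).
#' @param strata named integer vector of per-stratum sample sizes
#'   (names are ethnicity labels).
#' @param n_cpgs number of CpG probes simulated.
#' @param n_causal_cpgs number of CpGs with a planted effect on log cIMT.
#' @param causal_effect effect on ln(cIMT) of a one-unit change in
#'   methylation beta at a causal CpG.
#' @param noise_sd residual SD of ln(cIMT) (log-normal cIMT).
#' @param stratum_effect_multipliers optional named numeric vector, one per
#'   stratum, multiplying the causal effect in that stratum (injects
#'   between-stratum heterogeneity for I-squared tests). Default all 1.
#' @param region_scenarios character vector over
#'   \code{c("shared","distinct","null")} describing the colocalisation
#'   regions to simulate.
#' @param n_snps_per_region SNPs per simulated cis region (>= 2).
#' @param maf_range minor-allele-frequency range, within (0, 0.5).
#' @param ld_rho adjacent-SNP haplotype correlation of the AR(1) LD model.
#' @param cis_window_bp cis window in base pairs (default 1 Mb).
#' @param region_n_exp,region_n_out sample sizes of the exposure (meQTL) and
#'   outcome (GWAS/eQTL) cohorts behind regional summary statistics.
#' @param region_effect per-allele effect of the causal variant on the
#'   (standardised) exposure trait.
#' @param mediation_slope causal effect of the exposure on the outcome in
#'   the shared scenario; the outcome association at the shared variant is
#'   \code{mediation_slope * region_effect}, so the Wald ratio targets
#'   \code{mediation_slope}.
#' @param n_variants,n_genes cohort-level variant and gene counts for the
#'   meQTL/eQTL/eQTM planted truth.
#' @param meqtl_effect per-allele effect of a planted variant on CpG
#'   methylation, on the logit (M-value-like) scale.
#' @param eqtl_effect per-allele effect of a planted variant on expression.
#' @param eqtm_effect effect of methylation beta on expression for planted
#'   CpG-gene pairs.
#' @param logit_mean_sd SD of per-CpG mean methylation on the logit scale.
#' @param logit_sd between-sample SD of methylation on the logit scale.
#' @return an object of class \code{synth_config} (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         strata = c(chinese = 1000L, malay = 150L, indian = 150L),
                         n_cpgs = 2000L,
                         n_causal_cpgs = 3L,
                         causal_effect = 0.5,
                         noise_sd = 0.1,
                         stratum_effect_multipliers = NULL,
                         region_scenarios = c("shared", "distinct", "null"),
                         n_snps_per_region = 40L,
                         maf_range = c(0.1, 0.4),
                         ld_rho = 0.8,
                         cis_window_bp = 1e6,
                         region_n_exp = 5000L,
                         region_n_out = 5000L,
                         region_effect = 0.3,
                         mediation_slope = 0.5,
                         n_variants = 30L,
                         n_genes = 20L,
                         meqtl_effect = 0.3,
                         eqtl_effect = 0.4,
                         eqtm_effect = 3,
                         logit_mean_sd = 1.5,
                         logit_sd = 0.4) {
  if (is.null(names(strata)) || any(names(strata) == ""))
    stop("'strata' must be a named vector of sample sizes", call. = FALSE)
  strata <- vapply(strata, as.integer, integer(1))
  if (any(strata <= 0L))
    stop("all stratum sample sizes must be > 0", call. = FALSE)
  n_cpgs <- as.integer(n_cpgs); n_causal_cpgs <- as.integer(n_causal_cpgs)
  if (n_causal_cpgs > n_cpgs)
    stop("n_causal_cpgs must not exceed n_cpgs", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5)", call. = FALSE)
  region_scenarios <- match.arg(region_scenarios,
                                c("shared", "distinct", "null"),
                                several.ok = TRUE)
  if (is.null(stratum_effect_multipliers)) {
    stratum_effect_multipliers <- setNames(rep(1, length(strata)), names(strata))
  } else if (!all(names(strata) %in% names(stratum_effect_multipliers))) {
    stop("stratum_effect_multipliers must name every stratum", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), strata = strata, n_cpgs = n_cpgs,
    n_causal_cpgs = n_causal_cpgs, causal_effect = causal_effect,
    noise_sd = noise_sd,
    stratum_effect_multipliers = stratum_effect_multipliers,
    region_scenarios = region_scenarios,
    n_snps_per_region = as.integer(n_snps_per_region),
    maf_range = maf_range, ld_rho = ld_rho, cis_window_bp = cis_window_bp,
    region_n_exp = as.integer(region_n_exp),
    region_n_out = as.integer(region_n_out),
    region_effect = region_effect, mediation_slope = mediation_slope,
    n_variants = as.integer(n_variants), n_genes = as.integer(n_genes),
    meqtl_effect = meqtl_effect, eqtl_effect = eqtl_effect,
    eqtm_effect = eqtm_effect, logit_mean_sd = logit_mean_sd,
    logit_sd = logit_sd
  ), class = "synth_config")
}
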