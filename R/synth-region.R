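# Regional summary-statistic generator for the causal-inference module.

# Simulate dosages for n individuals at m SNPs with AR(1) haplotype
# correlation rho: each haplotype is a thresholded latent Gaussian AR(1)
# series, giving regional LD that decays geometrically with distance.
simulate_ld_dosage <- function(n, mafs, rho) {
  m <- length(mafs)
  thr <- qnorm(mafs)
  hap <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1L) {
      s <- sqrt(1 - rho^2)
      for (k in 2L:m) z[, k] <- rho * z[, k - 1L] + s * z[, k]
    }
    sweep(z, 2L, thr, "<") * 1L
  }
  hap() + hap()
}

# Vectorised per-variant marginal OLS of y on each dosage column.
marginal_sumstats <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2L, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  data.frame(beta = beta, se = se, p = p, n = n)
}

#' Generate exposure/outcome summary statistics for one cis region
#'
#' Simulates two independent cohorts genotyped at the same regional SNPs
#' (AR(1) haplotype LD) and returns marginal per-variant association
#' statistics for an exposure trait (e.g. CpG methylation) and an outcome
#' trait (e.g. disease liability or expression).  Three architectures are
#' supported: \code{"shared"} (one variant drives both traits; the outcome
#' effect is \code{mediation_slope * region_effect}, so the Wald ratio at
#' the shared variant targets \code{mediation_slope}), \code{"distinct"}
#' (two well-separated variants drive the two traits), and \code{"null"}
#' (no associated variant for either trait).
#'
#' @param config a [synth_config()]; uses \code{n_snps_per_region},
#'   \code{maf_range}, \code{ld_rho}, \code{region_n_exp},
#'   \code{region_n_out}, \code{region_effect}, \code{mediation_slope} and
#'   \code{seed}.
#' @param scenario one of \code{"shared"}, \code{"distinct"}, \code{"null"}.
#' @return a list with elements \code{exposure} and \code{outcome}, each a
#'   summary-statistics data frame (variant, chrom, pos, ea, oa, eaf, beta,
#'   se, p, n), plus \code{truth} recording the causal variant indices.
#' @examples
#' ss <- generate_region_sumstats(synth_config(seed = 3,
#'   region_n_exp = 500, region_n_out = 500), "shared")
#' head(ss$exposure)
#' @export
generate_region_sumstats <- function(config,
                                     scenario = c("shared", "distinct", "null")) {
  if (!inherits(config, "synth_config"))
    stop("'config' must be a synth_config object", call. = FALSE)
  scenario <- match.arg(scenario)
  m <- config$n_snps_per_region
  if (m < 2L)
    stop("n_snps_per_region must be at least 2", call. = FALSE)
  with_seed(config$seed, {
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
    pos <- 1e6L + seq_len(m) * 5000L
    ids <- sprintf("chr3:%d:A:G", pos)

    idx_exp <- idx_out <- NA_integer_
    if (scenario == "shared") {
      idx_exp <- idx_out <- as.integer(ceiling(m / 2))
    } else if (scenario == "distinct") {
      idx_exp <- as.integer(ceiling(m / 4))
      idx_out <- as.integer(ceiling(3 * m / 4))
    }

    g_exp <- simulate_ld_dosage(config$region_n_exp, mafs, config$ld_rho)
    y_exp <- rnorm(config$region_n_exp)
    if (!is.na(idx_exp))
      y_exp <- y_exp + config$region_effect * g_exp[, idx_exp]

    g_out <- simulate_ld_dosage(config$region_n_out, mafs, config$ld_rho)
    y_out <- rnorm(config$region_n_out)
    if (scenario == "shared") {
      y_out <- y_out + config$mediation_slope * config$region_effect *
        g_out[, idx_out]
    } else if (scenario == "distinct") {
      y_out <- y_out + config$region_effect * g_out[, idx_out]
    }

    mk <- function(G, y) {
      ss <- marginal_sumstats(G, y)
      data.frame(variant = ids, chrom = "chr3", pos = pos,
                 ea = "A", oa = "G", eaf = colMeans(G) / 2,
                 ss, stringsAsFactors = FALSE)
    }
    list(exposure = mk(g_exp, y_exp), outcome = mk(g_out, y_out),
         truth = list(scenario = scenario, idx_exposure = idx_exp,
                      idx_outcome = idx_out,
                      wald_ratio = if (scenario == "shared")
                        config$mediation_slope else NA_real_))
  })
}
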