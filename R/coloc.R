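# Bayesian colocalisation under the single-causal-variant assumption.

# Wakefield log approximate Bayes factor per variant from (beta, se).
# sd_prior is the prior SD of the effect at a truly associated variant.
wakefield_labf <- function(beta, se, sd_prior) {
  v <- se^2
  r <- sd_prior^2 / (sd_prior^2 + v)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + r * z2)
}

#' Bayesian colocalisation of two traits in one region
#'
#' Enumerates the five mutually exclusive single-causal-variant hypotheses
#' about a genomic region: H0 no association with either trait; H1/H2
#' association with trait A/B only; H3 both traits, distinct causal
#' variants; H4 both traits, one shared causal variant.  Per-variant
#' evidence is the Wakefield approximate Bayes factor computed from each
#' trait's effect estimate and standard error, with prior effect SD 0.15
#' for a quantitative trait and 0.2 for a case-control trait; hypothesis
#' posteriors sum the prior-weighted configuration likelihoods and are
#' normalised to 1.
#'
#' Variants are intersected on id; when both tables carry \code{ea}/\code{oa}
#' columns, a variant with swapped alleles in trait B is sign-flipped
#' (irrelevant to the ABF, which depends on z^2, but kept for consistency)
#' and strand-ambiguous (A/T, C/G) variants are retained with a warning
#' flag in the result (dosage data carry no strand ambiguity).
#'
#' @param traitA,traitB summary-statistics data frames (\code{variant,
#'   beta, se}); at least 2 shared variants required.  Rows with missing
#'   SE are dropped.
#' @param p1,p2 prior probability that a variant is causal for trait A / B
#'   only (default 1e-4 each).
#' @param p12 prior probability that a variant is causal for both traits
#'   (default 1e-5).
#' @param typeA,typeB \code{"quant"} or \code{"cc"}, selecting the prior
#'   effect SD (0.15 / 0.2).
#' @return a list of class \code{coloc_result}: \code{pp} (named posterior
#'   vector H0..H4 summing to 1), \code{priors}, \code{n_snps},
#'   \code{h4_h3_ratio}, \code{ambiguous_variants}.
#' @examples
#' ss <- generate_region_sumstats(synth_config(seed = 2,
#'   region_n_exp = 2000, region_n_out = 2000), "shared")
#' coloc_abf(ss$exposure, ss$outcome)$pp
#' @export
coloc_abf <- function(traitA, traitB, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      typeA = c("quant", "cc"), typeB = c("quant", "cc")) {
  typeA <- match.arg(typeA); typeB <- match.arg(typeB)
  for (nm in c("p1", "p2", "p12")) stopifnot_scalar_prob(get(nm), nm)
  a <- traitA[is.finite(traitA$se) & traitA$se > 0, , drop = FALSE]
  b <- traitB[is.finite(traitB$se) & traitB$se > 0, , drop = FALSE]
  common <- intersect(a$variant, b$variant)
  if (length(common) < 2L)
    stop("need at least 2 shared variants after intersection", call. = FALSE)
  ia <- match(common, a$variant); ib <- match(common, b$variant)
  ambiguous <- character(0)
  if (all(c("ea", "oa") %in% names(a)) && all(c("ea", "oa") %in% names(b))) {
    ea_a <- toupper(a$ea[ia]); oa_a <- toupper(a$oa[ia])
    ea_b <- toupper(b$ea[ib]); oa_b <- toupper(b$oa[ib])
    amb <- (ea_a == "A" & oa_a == "T") | (ea_a == "T" & oa_a == "A") |
      (ea_a == "C" & oa_a == "G") | (ea_a == "G" & oa_a == "C")
    if (any(amb)) {
      ambiguous <- common[amb]
      warning(length(ambiguous),
              " strand-ambiguous variant(s) retained (dosage data)")
    }
    swapped <- ea_b == oa_a & oa_b == ea_a
    aligned <- (ea_b == ea_a & oa_b == oa_a) | swapped
    keep <- aligned
    if (!all(keep)) {
      ia <- ia[keep]; ib <- ib[keep]; common <- common[keep]
      swapped <- swapped[keep]
      if (length(common) < 2L)
        stop("fewer than 2 allele-reconcilable shared variants", call. = FALSE)
    }
    b$beta[ib][swapped] <- -b$beta[ib][swapped]
  }
  sdA <- if (typeA == "quant") 0.15 else 0.2
  sdB <- if (typeB == "quant") 0.15 else 0.2
  la <- wakefield_labf(a$beta[ia], a$se[ia], sdA)
  lb <- wakefield_labf(b$beta[ib], b$se[ib], sdB)

  ls1 <- logsumexp(la)
  ls2 <- logsumexp(lb)
  ls12 <- logsumexp(la + lb)
  lH <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
    H4 = log(p12) + ls12)
  pp <- exp(lH - logsumexp(lH))
  pp <- pp / sum(pp)
  structure(list(
    pp = pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
    n_snps = length(common),
    h4_h3_ratio = pp[["H4"]] / pp[["H3"]],
    ambiguous_variants = ambiguous,
    labf = data.frame(variant = common, labf_A = la, labf_B = lb,
                      stringsAsFactors = FALSE)
  ), class = "coloc_result")
}

#' Sensitivity of colocalisation to the shared-causality prior
#'
#' Recomputes the colocalisation posteriors over a grid of \code{p12}
#' values and reports the robustness window: the range of grid values
#' satisfying \code{PP.H4 > 0.5} and \code{PP.H4/PP.H3 >= 3}.
#'
#' @param traitA,traitB as in [coloc_abf()].
#' @param p12_grid numeric grid of shared-causality priors, each in
#'   \code{(0, min(p1, p2)]}.
#' @param p1,p2 single-trait priors.
#' @param ... further arguments passed to [coloc_abf()].
#' @return list with \code{table} (one row per grid value: p12, PP.H0..H4,
#'   h4_h3_ratio, robust flag) and \code{robust_window} (min/max p12
#'   passing, or NA if none).
#' @export
p12_sensitivity <- function(traitA, traitB,
                            p12_grid = 10^seq(-6, -4.5, length.out = 7),
                            p1 = 1e-4, p2 = 1e-4, ...) {
  if (!length(p12_grid)) stop("empty p12 grid", call. = FALSE)
  if (any(p12_grid <= 0 | p12_grid > min(p1, p2)))
    stop("p12 grid values must lie in (0, min(p1, p2)]", call. = FALSE)
  p12_grid <- sort(p12_grid)
  rows <- lapply(p12_grid, function(p12) {
    cr <- coloc_abf(traitA, traitB, p1 = p1, p2 = p2, p12 = p12, ...)
    data.frame(p12 = p12, t(cr$pp), h4_h3_ratio = cr$h4_h3_ratio,
               robust = cr$pp[["H4"]] > 0.5 & cr$h4_h3_ratio >= 3)
  })
  tab <- do.call(rbind, rows)
  win <- if (any(tab$robust)) range(tab$p12[tab$robust]) else c(NA_real_, NA_real_)
  list(table = tab, robust_window = win)
}
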