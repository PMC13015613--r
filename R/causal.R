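# Instrument selection, Wald-ratio SMR, and evidence classification.

#' Select the genetic instrument for one exposure
#'
#' Scans an exposure summary-statistics table for variants with
#' \code{p < p_max} and instrument strength \code{F = (beta/se)^2 >=
#' f_min}, and returns the passing variant with the smallest P (ties broken
#' by larger F, then lexicographic variant id).  Variants with a zero or
#' missing standard error are skipped with a warning.
#'
#' @param exposure summary-statistics data frame (\code{variant, beta, se,
#'   p}, optionally \code{ea, oa, n}).
#' @param p_max instrument P-value ceiling (default 1e-5).
#' @param f_min minimum F statistic (default 10).
#' @return a list of class \code{instrument}: \code{found}, and when found
#'   \code{variant, beta_exp, se_exp, p_exp, F} plus alleles if present.
#' @export
select_instrument <- function(exposure, p_max = 1e-5, f_min = 10) {
  if (is.null(exposure) || !nrow(exposure))
    stop("empty exposure table", call. = FALSE)
  bad <- !is.finite(exposure$se) | exposure$se <= 0
  if (any(bad)) {
    warning(sum(bad), " variant(s) skipped (non-positive or missing SE)")
    exposure <- exposure[!bad, , drop = FALSE]
  }
  Fstat <- (exposure$beta / exposure$se)^2
  pass <- !is.na(exposure$p) & exposure$p < p_max & Fstat >= f_min
  if (!any(pass))
    return(structure(list(found = FALSE), class = "instrument"))
  cand <- exposure[pass, , drop = FALSE]
  Fc <- Fstat[pass]
  ord <- order(cand$p, -Fc, cand$variant)
  i <- ord[1]
  structure(list(
    found = TRUE, variant = cand$variant[i], beta_exp = cand$beta[i],
    se_exp = cand$se[i], p_exp = cand$p[i], F = Fc[i],
    ea = if ("ea" %in% names(cand)) cand$ea[i] else NA_character_,
    oa = if ("oa" %in% names(cand)) cand$oa[i] else NA_character_
  ), class = "instrument")
}

#' Wald-ratio summary-data Mendelian randomisation
#'
#' Single-instrument SMR estimate
#' \deqn{\hat\beta_{SMR} = \hat\beta_{outcome} / \hat\beta_{exposure}}
#' at the instrumental variant, tested with the statistic
#' \deqn{T = \frac{z_{exp}^2\, z_{out}^2}{z_{exp}^2 + z_{out}^2}}
#' referred to a chi-squared distribution with 1 df; the standard error is
#' back-derived as \code{|beta_smr| / sqrt(T)}.  If the outcome record's
#' effect/other alleles are swapped relative to the instrument, the outcome
#' beta is flipped; irreconcilable alleles raise an error.
#'
#' @param instrument an \code{instrument} from [select_instrument()].
#' @param outcome one-row summary statistics for the same variant
#'   (\code{beta, se}, optionally \code{ea, oa}).
#' @param outcome_label optional label carried into the result.
#' @return list of class \code{smr_result}: \code{beta_smr, se_smr, p_smr,
#'   T, instrument, outcome_label}.
#' @export
smr_wald <- function(instrument, outcome, outcome_label = NA_character_) {
  if (!inherits(instrument, "instrument") || !isTRUE(instrument$found))
    stop("a selected instrument is required", call. = FALSE)
  if (instrument$beta_exp == 0)
    stop("undefined Wald ratio: exposure beta is zero", call. = FALSE)
  b_out <- outcome$beta[1]; se_out <- outcome$se[1]
  if (!is.na(instrument$ea) && all(c("ea", "oa") %in% names(outcome))) {
    if (outcome$ea[1] == instrument$oa && outcome$oa[1] == instrument$ea) {
      b_out <- -b_out
    } else if (!(outcome$ea[1] == instrument$ea &&
                 outcome$oa[1] == instrument$oa)) {
      stop("allele mismatch between instrument and outcome", call. = FALSE)
    }
  }
  z_exp <- instrument$beta_exp / instrument$se_exp
  z_out <- b_out / se_out
  beta_smr <- b_out / instrument$beta_exp
  T <- if (z_out == 0) 0 else z_exp^2 * z_out^2 / (z_exp^2 + z_out^2)
  p <- pchisq(T, df = 1, lower.tail = FALSE)
  se_smr <- if (T > 0) abs(beta_smr) / sqrt(T) else Inf
  structure(list(beta_smr = beta_smr, se_smr = se_smr, p_smr = p, T = T,
                 instrument = instrument, outcome_label = outcome_label),
            class = "smr_result")
}

#' Classify triangulated causal evidence
#'
#' Applies the study's decision rule to one SMR result and one
#' colocalisation result for the same CpG-trait pair:
#' \code{supported_shared} when \code{p_smr < 0.05} and \code{PP.H4 > 0.5}
#' (methylation-mediated effect via a shared causal variant);
#' \code{flagged_H3} when \code{p_smr < 0.05} and \code{PP.H3 > 0.5}
#' (association for both traits but apparently distinct variants, e.g.
#' from cross-ancestry LD differences); otherwise \code{none}.
#'
#' @param smr an \code{smr_result}.
#' @param coloc a \code{coloc_result} from [coloc_abf()].
#' @param p_smr_max SMR significance threshold (default 0.05).
#' @param h4_min,h3_min posterior thresholds (default 0.5).
#' @return one of \code{"supported_shared"}, \code{"flagged_H3"},
#'   \code{"none"}.
#' @export
classify_evidence <- function(smr, coloc, p_smr_max = 0.05,
                              h4_min = 0.5, h3_min = 0.5) {
  sig <- smr$p_smr < p_smr_max
  if (sig && coloc$pp[["H4"]] > h4_min) return("supported_shared")
  if (sig && coloc$pp[["H3"]] > h3_min) return("flagged_H3")
  "none"
}
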