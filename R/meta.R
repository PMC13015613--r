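# Stouffer / IVW meta-analysis, heterogeneity, and the two-stage design.

#' Sample-size weighted Stouffer combination
#'
#' Combines per-study Z statistics with weights \eqn{w_i = \sqrt{n_i}}:
#' \deqn{Z_{meta} = \sum w_i z_i / \sqrt{\sum w_i^2}}
#' (the METAL convention), with a two-sided normal P.  Studies with missing
#' z or n are dropped; if none remain the probe is omitted (NA returned).
#'
#' @param z numeric vector of per-study Z statistics.
#' @param n numeric vector of per-study sample sizes (> 0).
#' @return list with \code{z_meta}, \code{p_meta}, \code{k} (studies used)
#'   and \code{direction} (one character per contributing study: +/-/?).
#' @examples
#' stouffer_combine(c(1, 1), c(100, 100))$z_meta  # sqrt(2)
#' @export
stouffer_combine <- function(z, n) {
  ok <- is.finite(z) & is.finite(n) & n > 0
  if (!any(ok))
    return(list(z_meta = NA_real_, p_meta = NA_real_, k = 0L, direction = ""))
  w <- sqrt(n[ok])
  z_meta <- sum(w * z[ok]) / sqrt(sum(w^2))
  dirs <- ifelse(is.finite(z), ifelse(z > 0, "+", ifelse(z < 0, "-", "0")), "?")
  list(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)), k = sum(ok),
       direction = paste(dirs, collapse = ""))
}

# Vectorised Stouffer across a probes x studies Z matrix and matching N
# matrix; NA entries are ignored per probe.
stouffer_combine_matrix <- function(Z, N) {
  W <- sqrt(N)
  W[!is.finite(Z)] <- NA
  num <- rowSums(W * Z, na.rm = TRUE)
  den <- sqrt(rowSums(W^2, na.rm = TRUE))
  z <- ifelse(den > 0, num / den, NA_real_)
  list(z = z, p = 2 * pnorm(-abs(z)),
       k = rowSums(is.finite(Z) & is.finite(N)))
}

#' Inverse-variance weighted fixed-effects combination
#'
#' \deqn{\beta_{meta} = \frac{\sum \beta_i / se_i^2}{\sum 1 / se_i^2},
#'   \qquad se_{meta} = \Big(\sum 1/se_i^2\Big)^{-1/2}}
#' Equivalent to the intercept of a weighted least-squares fit with weights
#' \eqn{1/se_i^2} and known unit residual variance.
#'
#' @param beta per-study effect estimates.
#' @param se per-study standard errors (> 0).
#' @return list with \code{beta_meta}, \code{se_meta}, \code{z}, \code{p}.
#' @examples
#' ivw_combine(c(1, 3), c(1, 1))$beta_meta  # 2
#' @export
ivw_combine <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and > 0", call. = FALSE)
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- sqrt(1 / sum(w))
  z <- beta_meta / se_meta
  list(beta_meta = beta_meta, se_meta = se_meta, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Cochran's Q and I-squared heterogeneity
#'
#' \eqn{Q = \sum w_i (\beta_i - \beta_{IVW})^2} with \eqn{w_i = 1/se_i^2},
#' referred to a chi-squared distribution with k-1 degrees of freedom;
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100} per cent.  Invariant to a
#' common positive rescaling of all (beta, se).
#'
#' @param beta per-study effect estimates (>= 2 studies).
#' @param se per-study standard errors.
#' @return list with \code{Q}, \code{q_p}, \code{i2} (per cent); all NA
#'   when fewer than 2 studies are supplied.
#' @examples
#' heterogeneity(c(0, 2), c(1, 1))  # Q = 2, I2 = 50
#' @export
heterogeneity <- function(beta, se) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[ok]; se <- se[ok]
  k <- length(beta)
  if (k < 2L) return(list(Q = NA_real_, q_p = NA_real_, i2 = NA_real_))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b)^2)
  q_p <- pchisq(Q, df = k - 1L, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - (k - 1L)) / Q) * 100 else 0
  list(Q = Q, q_p = q_p, i2 = i2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_threshold(0.05, 53466)  # 9.35e-07
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot_scalar_prob(alpha, "alpha")
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("'m' must be a positive number of tests", call. = FALSE)
  alpha / m
}

#' Two-stage discovery meta-analysis
#'
#' Stage 1 applies the sample-size weighted Stouffer method across the
#' discovery studies (e.g. the Asian ethnic strata) and carries forward
#' probes with \code{p < stage1_alpha}.  Stage 2 re-combines the discovery
#' studies together with any additional studies (e.g. European cohorts),
#' restricted to carried-forward probes present in every contributing
#' dataset -- a 450K-array study therefore contributes only at sites
#' overlapping both platforms, and the availability fraction is reported.
#' Sentinels are probes whose stage-2 P falls below the subset Bonferroni
#' threshold \code{stage2_alpha / n_stage2_tests}.
#'
#' @param stage1 list of per-study association data frames (columns
#'   \code{probe, z, p, n}; \code{beta}/\code{se} used for heterogeneity
#'   when present).
#' @param stage2_extra optional list of additional study data frames with
#'   the same columns; a study's probe set acts as its platform mask.
#' @param stage1_alpha carry-forward threshold (default 0.05).
#' @param stage2_alpha family-wise alpha for the subset Bonferroni
#'   threshold (default 0.05).
#' @param complete_studies require a probe in every study of a stage
#'   (default TRUE, matching the availability accounting); FALSE combines
#'   whatever studies cover each probe.
#' @return list with \code{stage1} and \code{stage2} results data frames
#'   (probe, z, p, k, direction, and i2/q_p when computable),
#'   \code{survivors}, \code{n_stage2_tests}, \code{availability} (fraction
#'   of survivors testable in stage 2), \code{threshold}, and
#'   \code{sentinels}.
#' @export
two_stage_meta <- function(stage1, stage2_extra = NULL,
                           stage1_alpha = 0.05, stage2_alpha = 0.05,
                           complete_studies = TRUE) {
  if (!is.list(stage1) || !length(stage1))
    stop("'stage1' must be a non-empty list of study data frames", call. = FALSE)
  s1 <- meta_stage(stage1, complete_studies)
  survivors <- s1$probe[!is.na(s1$p) & s1$p < stage1_alpha]
  if (!length(survivors)) stop("no probes pass stage 1", call. = FALSE)

  studies2 <- c(stage1, if (!is.null(stage2_extra)) stage2_extra)
  if (complete_studies) {
    present <- Reduce(intersect, lapply(studies2, `[[`, "probe"))
    testable <- intersect(survivors, present)
  } else testable <- survivors
  if (!length(testable)) stop("empty stage-2 probe set", call. = FALSE)
  s2 <- meta_stage(lapply(studies2, function(d) d[d$probe %in% testable, ]),
                   complete_studies)
  n_tests <- nrow(s2)
  threshold <- bonferroni_threshold(stage2_alpha, n_tests)
  sentinels <- s2[!is.na(s2$p) & s2$p < threshold, , drop = FALSE]
  sentinels <- sentinels[order(sentinels$p), , drop = FALSE]
  list(stage1 = s1, stage2 = s2, survivors = survivors,
       n_stage2_tests = n_tests,
       availability = length(testable) / length(survivors),
       threshold = threshold, sentinels = sentinels)
}

# Stouffer-combine a list of study tables over their (common) probes.
meta_stage <- function(studies, complete_studies = TRUE) {
  probes <- if (complete_studies)
    Reduce(intersect, lapply(studies, `[[`, "probe"))
  else unique(unlist(lapply(studies, `[[`, "probe")))
  k <- length(studies)
  Z <- N <- matrix(NA_real_, length(probes), k)
  B <- SE <- matrix(NA_real_, length(probes), k)
  has_bse <- all(vapply(studies, function(d)
    all(c("beta", "se") %in% names(d)), logical(1)))
  for (i in seq_len(k)) {
    m <- match(probes, studies[[i]]$probe)
    Z[, i] <- studies[[i]]$z[m]
    N[, i] <- studies[[i]]$n[m]
    if (has_bse) { B[, i] <- studies[[i]]$beta[m]; SE[, i] <- studies[[i]]$se[m] }
  }
  sc <- stouffer_combine_matrix(Z, N)
  dir <- apply(Z, 1L, function(z)
    paste(ifelse(is.na(z), "?", ifelse(z > 0, "+", ifelse(z < 0, "-", "0"))),
          collapse = ""))
  out <- data.frame(probe = probes, z = sc$z, p = sc$p, k = sc$k,
                    n_eff = rowSums(N, na.rm = TRUE), direction = dir,
                    stringsAsFactors = FALSE)
  if (has_bse && k >= 2L) {
    het <- t(vapply(seq_len(nrow(B)), function(j) {
      h <- heterogeneity(B[j, ], SE[j, ])
      c(h$Q, h$q_p, h$i2)
    }, numeric(3)))
    out$Q <- het[, 1]; out$q_p <- het[, 2]; out$i2 <- het[, 3]
  }
  out
}

#' Agreement diagnostics between two sets of meta-analytic Z statistics
#'
#' Spearman rank correlation and sign concordance over the probes common to
#' two analyses (e.g. Stouffer vs IVW within one ancestry).  Probes with a
#' zero Z in either set are excluded from the concordance denominator.
#'
#' @param zA,zB named numeric vectors of per-probe Z statistics (names are
#'   probe ids), or two data frames with \code{probe} and \code{z} columns.
#' @return list with \code{rho}, \code{sign_concordance} (per cent) and
#'   \code{n_common}.
#' @export
concordance_diagnostics <- function(zA, zB) {
  if (is.data.frame(zA)) zA <- setNames(zA$z, zA$probe)
  if (is.data.frame(zB)) zB <- setNames(zB$z, zB$probe)
  common <- intersect(names(zA), names(zB))
  if (length(common) < 3L)
    stop("need at least 3 common probes", call. = FALSE)
  a <- zA[common]; b <- zB[common]
  rho <- cor(a, b, method = "spearman", use = "complete.obs")
  nz <- a != 0 & b != 0 & !is.na(a) & !is.na(b)
  conc <- 100 * mean(sign(a[nz]) == sign(b[nz]))
  list(rho = rho, sign_concordance = conc, n_common = length(common))
}

#' Fraction of signals specific to the discovery analysis
#'
#' Among probes with \code{pA < alpha} (detectable association in analysis
#' A), the percentage with \code{pB >= alpha} (no corresponding evidence in
#' analysis B) -- the discovery-specific accounting used when comparing an
#' ancestry-focused screen with another ancestry's meta-analysis.
#'
#' @param pA,pB named per-probe p-value vectors (names are probe ids).
#' @param alpha detection threshold (default 0.05).
#' @return list with \code{pct} (per cent), \code{n_specific} and
#'   \code{n_detected}.
#' @export
discovery_specific_rate <- function(pA, pB, alpha = 0.05) {
  common <- intersect(names(pA), names(pB))
  if (!length(common)) stop("no common probes", call. = FALSE)
  a <- pA[common]; b <- pB[common]
  det <- !is.na(a) & a < alpha
  spec <- det & !is.na(b) & b >= alpha
  list(pct = 100 * sum(spec) / sum(det), n_specific = sum(spec),
       n_detected = sum(det))
}
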