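# Per-stratum linear-model association of CpG methylation with ln(cIMT).

# Build a design matrix from a covariate data frame, dropping columns that
# are constant after listwise deletion (e.g. smoking in a small stratum).
# Returns list(X, dropped).
build_design <- function(covariates, n) {
  if (is.null(covariates) || !length(covariates))
    return(list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                dropped = character(0)))
  keep <- vapply(covariates, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) > 1L
  }, logical(1))
  dropped <- names(covariates)[!keep]
  covariates <- covariates[, keep, drop = FALSE]
  X <- if (ncol(covariates))
    model.matrix(~ ., data = covariates)
  else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  list(X = X, dropped = dropped)
}

#' Association of one CpG with a quantitative outcome
#'
#' Ordinary least squares of the outcome (natural-log cIMT in the EWAS) on
#' the CpG beta value plus covariates, after listwise deletion.  The test
#' statistic is the coefficient t ratio, with a two-sided P from the t
#' distribution on the residual degrees of freedom (strata can be small,
#' so a normal reference is not used).  Covariates that are constant after
#' deletion are dropped rather than erroring; a genuinely collinear design
#' raises a singular-design error naming the offending columns.
#'
#' @param y numeric outcome vector.
#' @param cpg numeric methylation beta vector.
#' @param covariates optional data frame of covariates (factors allowed).
#' @param probe,stratum optional labels carried into the result.
#' @return one-row data frame: \code{probe, stratum, beta, se, z, p, n,
#'   degenerate} (z is the t statistic; \code{degenerate} flags an exact
#'   fit with zero residual variance).  Dropped covariates are recorded in
#'   the \code{"dropped"} attribute.
#' @examples
#' set.seed(1)
#' x <- runif(100); y <- 0.5 * x + rnorm(100, 0, 0.1)
#' fit_cpg_association(y, x)
#' @export
fit_cpg_association <- function(y, cpg, covariates = NULL,
                                probe = NA_character_,
                                stratum = NA_character_) {
  df <- data.frame(.y = y, .cpg = cpg)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  des <- build_design(df[, setdiff(names(df), c(".y", ".cpg")), drop = FALSE], n)
  X <- cbind(des$X, cpg = df$.cpg)
  if (n < ncol(X) + 2L)
    stop("too few complete cases (", n, ") for ", ncol(X), " parameters",
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, df$.y)
  dfres <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dfres
  XtXinv_last <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
  beta <- unname(fit$coefficients["cpg"])
  se <- sqrt(sigma2 * XtXinv_last)
  tol <- 1e-12 * max(1, sum(df$.y^2))
  degenerate <- rss <= tol
  z <- if (se > 0) beta / se else sign(beta) * Inf
  p <- if (se > 0) 2 * pt(-abs(z), dfres) else 0
  out <- data.frame(probe = probe, stratum = stratum, beta = beta, se = se,
                    z = z, p = p, n = n, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- des$dropped
  out
}

#' Stratified epigenome-wide association scan
#'
#' Fits the per-CpG model of [fit_cpg_association()] for every probe within
#' every stratum independently; strata may use different covariate sets
#' (supply a named list) and a stratum below \code{min_n} samples is
#' skipped with a warning.  When a stratum's methylation has no missing
#' values the scan uses a residualisation fast path that is numerically
#' identical to the per-probe fit; probes with missing values fall back to
#' per-probe listwise deletion so each probe's n is recorded for
#' sample-size-weighted meta-analysis.
#'
#' @param bundle a \code{cohort_bundle}, or a list with \code{methylation}
#'   (values + manifest) and \code{samples} (with \code{stratum} and
#'   \code{cimt_mean}).
#' @param covariates character vector of sample columns used as covariates
#'   (default: age, sex, smoking, five cell proportions, five technical
#'   PCs), or a named list giving one vector per stratum.
#' @param min_n minimum stratum size.
#' @return data frame with one row per (probe, stratum): \code{probe,
#'   stratum, chrom, pos, beta, se, z, p, n}.  Attributes: \code{"dropped"}
#'   (named list of covariates dropped per stratum) and \code{"lambda"}
#'   (per-stratum genomic-control inflation diagnostic, reported only).
#' @export
run_stratified_ewas <- function(bundle,
                                covariates = c("age", "sex", "smoking",
                                               "cd4t", "cd8t", "bcell", "nk",
                                               "mono", paste0("pc", 1:5)),
                                min_n = 30L) {
  meth <- bundle$methylation
  samples <- bundle$samples
  y_all <- log(samples$cimt_mean)
  strata <- unique(samples$stratum)
  res <- list(); dropped <- list(); lambda <- c()
  for (s in strata) {
    idx <- which(samples$stratum == s)
    if (length(idx) < min_n) {
      warning("stratum '", s, "' has n=", length(idx),
              " < min_n; skipped")
      next
    }
    covs <- if (is.list(covariates)) covariates[[s]] else covariates
    covs <- intersect(covs, names(samples))
    cdf <- samples[idx, covs, drop = FALSE]
    y <- y_all[idx]
    M <- meth$values[idx, , drop = FALSE]
    des <- build_design(cdf, length(idx))
    dropped[[s]] <- des$dropped
    X <- des$X
    if (qr(X)$rank < ncol(X))
      stop("singular covariate design in stratum '", s, "'", call. = FALSE)
    if (!anyNA(M) && !anyNA(y)) {
      st <- ewas_fast(y, M, X)
    } else {
      st <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
        f <- fit_cpg_association(y, M[, j], cdf)
        f[, c("beta", "se", "z", "p", "n")]
      }))
    }
    st$probe <- colnames(M)
    st$stratum <- s
    lambda[s] <- median(st$z^2, na.rm = TRUE) / qchisq(0.5, 1)
    res[[s]] <- st
  }
  if (!length(res)) stop("no stratum met the minimum sample size", call. = FALSE)
  out <- do.call(rbind, res)
  m <- match(out$probe, meth$manifest$id)
  out <- data.frame(probe = out$probe, stratum = out$stratum,
                    chrom = meth$manifest$chrom[m],
                    pos = meth$manifest$pos[m],
                    out[, c("beta", "se", "z", "p", "n")],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "lambda") <- lambda
  out
}

# Residualisation (Frisch-Waugh-Lovell) fast path: project outcome and all
# probes off the covariate design, then per-probe simple regression with
# df = n - ncol(X) - 1. Identical to per-probe OLS when data are complete.
ewas_fast <- function(y, M, X) {
  n <- length(y)
  qx <- qr(X)
  ry <- qr.resid(qx, y)
  RM <- qr.resid(qx, M)
  sxx <- colSums(RM^2)
  sxy <- as.vector(crossprod(RM, ry))
  ryy <- sum(ry^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  dfres <- n - ncol(X) - 1L
  rss <- pmax(ryy - beta * sxy, 0)
  se <- sqrt(rss / dfres / sxx)
  z <- beta / se
  p <- 2 * pt(-abs(z), dfres)
  data.frame(beta = beta, se = se, z = z, p = p, n = n)
}
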