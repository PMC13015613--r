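# Methylation quantification and quality control.

#' Beta value from methylated/unmethylated intensities
#'
#' Computes the methylation beta value \eqn{\beta = M / (M + U + 100)},
#' where 100 is the fixed offset stabilising the ratio at low total
#' intensity.  Strictly below 1 for finite inputs; monotone increasing in
#' M and decreasing in U.  Vectorised.
#'
#' @param m methylated signal(s), non-negative.
#' @param u unmethylated signal(s), non-negative.
#' @return beta value(s) in [0, 1).
#' @examples
#' beta_from_intensities(900, 0)   # 0.9
#' beta_from_intensities(450, 450) # 0.45
#' @export
beta_from_intensities <- function(m, u) {
  if (any(!is.finite(m)) || any(!is.finite(u)) || any(m < 0) || any(u < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  m / (m + u + 100)
}

#' Filter markers by call rate and probe class
#'
#' Removes probes whose call rate (fraction of non-missing samples) is
#' below \code{min_callrate} and, optionally, probes targeting non-CpG
#' sites.  Reasons are logged non-exclusively (a probe may fail both
#' checks) alongside the count actually removed.  Re-applicable to sample
#' subsets for a second round of call-rate filtering.
#'
#' @param matrix_ a methylation matrix list with \code{values} (samples x
#'   probes, missing allowed) and \code{manifest} (with \code{id} and
#'   optionally \code{class} columns), e.g. the \code{methylation} element
#'   of a cohort bundle.
#' @param min_callrate minimum per-probe call rate in (0, 1].
#' @param drop_non_cpg drop probes whose manifest class is not "CpG"?
#' @return list with the filtered \code{matrix_} and an exclusion
#'   \code{log} (named counts: \code{callrate}, \code{non_cpg},
#'   \code{removed}, \code{retained}).
#' @export
filter_markers <- function(matrix_, min_callrate = 0.95, drop_non_cpg = TRUE) {
  if (!is.list(matrix_) || is.null(matrix_$values) || !ncol(matrix_$values))
    stop("empty methylation matrix", call. = FALSE)
  if (min_callrate <= 0 || min_callrate > 1)
    stop("min_callrate must be in (0, 1]", call. = FALSE)
  vals <- matrix_$values
  man <- matrix_$manifest
  callrate <- colMeans(!is.na(vals))
  low <- callrate < min_callrate
  non_cpg <- if (drop_non_cpg && !is.null(man$class))
    man$class[match(colnames(vals), man$id)] != "CpG"
  else rep(FALSE, ncol(vals))
  drop <- low | non_cpg
  out <- matrix_
  out$values <- vals[, !drop, drop = FALSE]
  out$manifest <- man[man$id %in% colnames(out$values), , drop = FALSE]
  list(matrix_ = out,
       log = c(callrate = sum(low), non_cpg = sum(non_cpg),
               removed = sum(drop), retained = sum(!drop)))
}

#' Exclude flagged samples
#'
#' Removes samples flagged for sex mismatch (reported vs inferred),
#' duplication, or array scan failure.  A sample flagged for several
#' reasons is removed once and attributed to the first reason in the fixed
#' precedence \code{sex_mismatch > duplicate > scan_fail}, keeping
#' exclusion logs reproducible.  Idempotent.
#'
#' @param matrix_ methylation matrix list (samples x probes in
#'   \code{values}).
#' @param annotations data frame with a sample \code{id} column and logical
#'   flag columns named after the rules.
#' @param rules character vector of rules to apply, a subset of
#'   \code{c("sex_mismatch", "duplicate", "scan_fail")}.
#' @return list with the filtered \code{matrix_}, the filtered
#'   \code{annotations}, and a \code{log} of per-reason counts.
#' @export
exclude_samples <- function(matrix_, annotations,
                            rules = c("sex_mismatch", "duplicate", "scan_fail")) {
  order_ <- c("sex_mismatch", "duplicate", "scan_fail")
  if (!all(rules %in% order_))
    stop("unknown exclusion rule(s): ",
         paste(setdiff(rules, order_), collapse = ", "), call. = FALSE)
  rules <- order_[order_ %in% rules]
  ids <- rownames(matrix_$values)
  ann <- annotations[match(ids, annotations$id), , drop = FALSE]
  reason <- rep(NA_character_, length(ids))
  for (r in rules) {
    flag <- if (r %in% names(ann)) ann[[r]] %in% TRUE else rep(FALSE, length(ids))
    reason[is.na(reason) & flag] <- r
  }
  keep <- is.na(reason)
  out <- matrix_
  out$values <- matrix_$values[keep, , drop = FALSE]
  log_ <- setNames(vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                          numeric(1)), rules)
  list(matrix_ = out, annotations = ann[keep, , drop = FALSE],
       log = c(log_, removed = sum(!keep), retained = sum(keep)))
}

#' Quantile normalisation across samples
#'
#' Forces every sample's marginal distribution onto the cross-sample mean
#' order statistics while preserving within-sample ranks.  Missing values
#' are allowed: each sample is normalised over its non-missing entries,
#' interpolating the mean order statistics to the sample's own count
#' (delegates to \code{limma::normalizeQuantiles} with \code{ties = TRUE}).
#'
#' @param matrix_ methylation matrix list with \code{values} samples x
#'   probes, or a bare numeric matrix (samples in rows).
#' @return the same structure with normalised values.
#' @export
quantile_normalize <- function(matrix_) {
  bare <- is.matrix(matrix_)
  vals <- if (bare) matrix_ else matrix_$values
  if (nrow(vals) < 2L) {
    warning("quantile normalisation requires >= 2 samples; returning input unchanged")
    return(matrix_)
  }
  # limma normalises columns; our samples are rows
  norm <- t(limma::normalizeQuantiles(t(vals), ties = TRUE))
  dimnames(norm) <- dimnames(vals)
  if (bare) return(norm)
  matrix_$values <- norm
  matrix_
}
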