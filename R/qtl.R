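# cis-window QTL mapping: meQTL (dosage -> beta), eQTL (dosage ->
# expression) and eQTM (beta -> expression).

#' Enumerate cis feature-partner pairs
#'
#' All same-chromosome pairs whose positions differ by at most
#' \code{window} base pairs.  The bound is inclusive: a partner at exactly
#' the window distance is retained.  Gene anchors are the transcription
#' start positions supplied in the manifest.
#'
#' @param anchors data frame of features with \code{id, chrom, pos}
#'   columns (\code{tss} accepted as position for gene manifests).
#' @param partners data frame with \code{id, chrom, pos}.
#' @param window cis window in base pairs (default 1e6).
#' @return data frame: \code{feature, partner, chrom, pos_feature,
#'   pos_partner, distance} (signed partner - feature). Empty when no pair
#'   qualifies.
#' @export
enumerate_cis_pairs <- function(anchors, partners, window = 1e6) {
  poscol <- function(d) if ("pos" %in% names(d)) d$pos else d$tss
  a <- data.frame(id = anchors$id, chrom = anchors$chrom,
                  pos = poscol(anchors), stringsAsFactors = FALSE)
  b <- data.frame(id = partners$id, chrom = partners$chrom,
                  pos = poscol(partners), stringsAsFactors = FALSE)
  out <- merge(a, b, by = "chrom", suffixes = c("_feature", "_partner"))
  out$distance <- out$pos_partner - out$pos_feature
  out <- out[abs(out$distance) <= window, , drop = FALSE]
  data.frame(feature = out$id_feature, partner = out$id_partner,
             chrom = out$chrom, pos_feature = out$pos_feature,
             pos_partner = out$pos_partner, distance = out$distance,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit one cis-QTL association
#'
#' OLS of the outcome on the predictor plus covariates -- SNP dosage on
#' methylation (meQTL), dosage on expression (eQTL) or methylation beta on
#' expression (eQTM).  Reuses the EWAS fitting engine, so missing-data
#' handling, covariate dropping and the t-based P are identical.
#'
#' @param predictor,outcome numeric vectors.
#' @param covariates optional covariate data frame.
#' @param kind one of \code{"meQTL"}, \code{"eQTL"}, \code{"eQTM"}.
#' @param feature,partner,cohort optional labels.
#' @return one-row data frame: \code{feature, partner, kind, cohort, beta,
#'   se, z, p, n}.
#' @export
fit_qtl <- function(predictor, outcome, covariates = NULL,
                    kind = c("meQTL", "eQTL", "eQTM"),
                    feature = NA_character_, partner = NA_character_,
                    cohort = NA_character_) {
  kind <- match.arg(kind)
  f <- fit_cpg_association(outcome, predictor, covariates)
  data.frame(feature = feature, partner = partner, kind = kind,
             cohort = cohort, beta = f$beta, se = f$se, z = f$z, p = f$p,
             n = f$n, stringsAsFactors = FALSE)
}

#' Cross-cohort IVW meta-analysis of QTL results
#'
#' Combines per-cohort estimates of the same feature-variant pair by
#' fixed-effects inverse-variance weighting, after aligning effect alleles:
#' a cohort whose effect/other alleles are swapped relative to the first
#' cohort has its beta negated; irreconcilable alleles raise an error.
#'
#' @param results list of one-row QTL data frames (from [fit_qtl()] or
#'   summary tables), optionally carrying \code{ea}/\code{oa} allele
#'   columns.
#' @return one-row data frame with the combined \code{beta, se, z, p} and
#'   summed \code{n}.
#' @export
meta_qtl <- function(results) {
  if (!length(results)) stop("no results to combine", call. = FALSE)
  d <- do.call(rbind, lapply(results, function(r)
    r[, intersect(c("feature", "partner", "kind", "beta", "se", "n",
                    "ea", "oa"), names(r)), drop = FALSE]))
  if (all(c("ea", "oa") %in% names(d))) {
    ref_ea <- d$ea[1]; ref_oa <- d$oa[1]
    flip <- d$ea == ref_oa & d$oa == ref_ea
    bad <- !flip & !(d$ea == ref_ea & d$oa == ref_oa)
    if (any(bad))
      stop("irreconcilable alleles across cohorts", call. = FALSE)
    d$beta[flip] <- -d$beta[flip]
  }
  m <- ivw_combine(d$beta, d$se)
  data.frame(feature = d$feature[1], partner = d$partner[1],
             kind = if ("kind" %in% names(d)) d$kind[1] else NA_character_,
             beta = m$beta_meta, se = m$se_meta, z = m$z, p = m$p,
             n = sum(d$n), stringsAsFactors = FALSE)
}

#' Map all cis pairs of one kind in a cohort bundle
#'
#' Convenience scan: enumerates cis pairs with [enumerate_cis_pairs()] and
#' fits each with [fit_qtl()].
#'
#' @param bundle a \code{cohort_bundle}.
#' @param kind \code{"meQTL"} (dosage -> methylation beta), \code{"eQTL"}
#'   (dosage -> expression) or \code{"eQTM"} (beta -> expression).
#' @param covariates character vector of sample columns (default age,
#'   sex); pass NULL for none.
#' @param window cis window in bp.
#' @return data frame of per-pair results.
#' @export
run_cis_scan <- function(bundle, kind = c("meQTL", "eQTL", "eQTM"),
                         covariates = c("age", "sex"), window = 1e6) {
  kind <- match.arg(kind)
  probes <- bundle$methylation$manifest
  variants <- bundle$genotypes$manifest
  genes <- bundle$expression$manifest
  pairs <- switch(kind,
    meQTL = enumerate_cis_pairs(probes, variants, window),
    eQTL = enumerate_cis_pairs(genes, variants, window),
    eQTM = enumerate_cis_pairs(genes, probes, window))
  if (!nrow(pairs)) return(pairs)
  cdf <- if (is.null(covariates)) NULL else
    bundle$samples[, intersect(covariates, names(bundle$samples)), drop = FALSE]
  getvec <- function(kind_side, id) switch(kind_side,
    probe = bundle$methylation$values[, id],
    variant = bundle$genotypes$dosage[, id],
    gene = bundle$expression$values[id, ])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    pred <- switch(kind,
      meQTL = getvec("variant", pairs$partner[i]),
      eQTL = getvec("variant", pairs$partner[i]),
      eQTM = getvec("probe", pairs$partner[i]))
    outc <- switch(kind,
      meQTL = bundle$methylation$values[, pairs$feature[i]],
      eQTL = getvec("gene", pairs$feature[i]),
      eQTM = getvec("gene", pairs$feature[i]))
    fit_qtl(pred, outc, cdf, kind = kind,
            feature = pairs$feature[i], partner = pairs$partner[i])
  })
  cbind(pairs[, c("chrom", "pos_feature", "pos_partner", "distance")],
        do.call(rbind, out))[, c("feature", "partner", "kind", "chrom",
                                 "pos_feature", "pos_partner", "distance",
                                 "cohort", "beta", "se", "z", "p", "n")]
}
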