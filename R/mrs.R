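# Methylation risk score: derivation, scoring, clinical-threshold
# classification and evaluation.

#' Derive MRS weights from a training cohort
#'
#' For each sentinel CpG, fits \code{ln(cIMT) ~ CpG + covariates}
#' separately within each ethnicity and combines the per-ethnicity z
#' statistics by sample-size weighted Stouffer meta-analysis; the combined
#' z is the CpG's weight.  The \code{"basic"} model adjusts for age and
#' sex only (guarding against overfitting at small n); the
#' \code{"comprehensive"} variant uses the full EWAS covariate set
#' (smoking, cell proportions, technical PCs).  A sentinel that is
#' constant within an ethnicity has that stratum skipped for that CpG,
#' with a log entry.
#'
#' @param bundle a \code{cohort_bundle} (or list with \code{methylation}
#'   and \code{samples}) restricted to the training samples.
#' @param sentinels character vector of sentinel CpG ids; all must be
#'   present in the methylation matrix.
#' @param model \code{"basic"} or \code{"comprehensive"}.
#' @param comprehensive_covariates covariates of the comprehensive model.
#' @return list of class \code{mrs_model}: \code{cpgs}, \code{weights}
#'   (named, Stouffer-combined z), \code{model}, \code{details} (per
#'   CpG-stratum fits), \code{log}.
#' @export
derive_weights <- function(bundle, sentinels,
                           model = c("basic", "comprehensive"),
                           comprehensive_covariates = c("age", "sex",
                             "smoking", "cd4t", "cd8t", "bcell", "nk",
                             "mono", paste0("pc", 1:5))) {
  model <- match.arg(model)
  meth <- bundle$methylation$values
  samples <- bundle$samples
  missing_ <- setdiff(sentinels, colnames(meth))
  if (length(missing_))
    stop("sentinel CpG(s) absent from training methylation: ",
         paste(missing_, collapse = ", "), call. = FALSE)
  covs <- if (model == "basic") c("age", "sex") else comprehensive_covariates
  covs <- intersect(covs, names(samples))
  strata <- unique(samples$stratum)
  details <- list(); log_ <- character(0)
  weights <- setNames(numeric(length(sentinels)), sentinels)
  for (cpg in sentinels) {
    zs <- ns <- c()
    for (s in strata) {
      idx <- samples$stratum == s
      b <- meth[idx, cpg]
      if (length(unique(b[!is.na(b)])) < 2L) {
        log_ <- c(log_, sprintf("%s constant in stratum '%s'; skipped", cpg, s))
        next
      }
      f <- fit_cpg_association(log(samples$cimt_mean[idx]), b,
                               samples[idx, covs, drop = FALSE],
                               probe = cpg, stratum = s)
      details[[paste(cpg, s)]] <- f
      zs <- c(zs, f$z); ns <- c(ns, f$n)
    }
    if (!length(zs))
      stop("sentinel ", cpg, " constant in every stratum", call. = FALSE)
    weights[cpg] <- stouffer_combine(zs, ns)$z_meta
  }
  structure(list(cpgs = sentinels, weights = weights, model = model,
                 details = do.call(rbind, details), log = log_),
            class = "mrs_model")
}

#' Score samples with an MRS model
#'
#' \deqn{MRS = \sum_i w_i b_i} where \eqn{b_i} is the per-CpG rank-based
#' inverse-normal transform of methylation beta across the scored samples
#' (making scores invariant to any per-CpG monotone transform of raw
#' betas) and \eqn{w_i} the model weights.  A sample missing any model CpG
#' is scored missing.
#'
#' @param model an \code{mrs_model}.
#' @param methylation samples x probes beta matrix (or a methylation
#'   matrix list with \code{values}).
#' @return named numeric vector of scores, one per sample row.
#' @export
compute_mrs <- function(model, methylation) {
  vals <- if (is.list(methylation)) methylation$values else methylation
  missing_ <- setdiff(model$cpgs, colnames(vals))
  if (length(missing_))
    stop("model CpG(s) absent: ", paste(missing_, collapse = ", "),
         call. = FALSE)
  B <- vals[, model$cpgs, drop = FALSE]
  Bn <- apply(B, 2L, inverse_normal)
  score <- as.vector(Bn %*% model$weights[model$cpgs])
  score[!complete.cases(B)] <- NA_real_
  setNames(score, rownames(vals))
}

# Locate the normative-table row for each (age, sex, ethnicity); errors on
# ages outside the supported bands.
lookup_normative <- function(table_, age, sex, ethnicity) {
  n <- length(age)
  idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    in_band <- age[i] >= table_$age_lower &
      (age[i] < table_$age_upper |
         (age[i] == table_$age_upper & table_$age_upper == max(table_$age_upper)))
    hit <- which(in_band & table_$sex == sex[i] & table_$ethnicity == ethnicity[i])
    if (length(hit)) idx[i] <- hit[1]
  }
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("no normative reference for ", length(bad), " sample(s) ",
         "(e.g. age ", age[bad[1]], ", ", sex[bad[1]], ", ",
         ethnicity[bad[1]], "); ages above the supported bands must be ",
         "excluded upstream", call. = FALSE)
  }
  idx
}

#' Classify elevated cIMT against a normative table
#'
#' Flags cIMT at or above the age-, sex- and ethnicity-specific 75th
#' percentile of the normative table (a value exactly at the percentile is
#' elevated; set \code{strict = TRUE} for the strictly-above variant).
#' Ages outside the table's bands (e.g. above 80 years) raise an error:
#' such participants have no normative reference and are excluded
#' upstream.
#'
#' @param cimt cIMT values (mm).
#' @param age,sex,ethnicity sample characteristics (vectors recycled to
#'   the length of \code{cimt}).
#' @param table_ a \code{normative_table} from
#'   [generate_normative_table()].
#' @param strict use strictly-greater instead of at-or-above.
#' @return logical vector.
#' @export
classify_elevated <- function(cimt, age, sex, ethnicity, table_,
                              strict = FALSE) {
  idx <- lookup_normative(table_, age, sex, ethnicity)
  p75 <- table_$p75[idx]
  if (strict) cimt > p75 else cimt >= p75
}

#' Stratified train/test split
#'
#' Allocates samples to a training fraction within each stratum cell
#' (ethnicity x elevated status by default) using largest-remainder
#' rounding, so the per-cell elevated fraction differs between train and
#' test by at most one sample and the overall training size is
#' \code{round(train_frac * n)}.  Deterministic given the seed.
#'
#' @param samples data frame with an \code{id} column and the stratum
#'   columns.
#' @param train_frac training fraction (default 0.7).
#' @param strata_cols columns defining the cells (default
#'   \code{c("stratum", "elevated")}).
#' @param seed RNG seed.
#' @return list with \code{train} and \code{test} id vectors (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(samples, train_frac = 0.7,
                             strata_cols = c("stratum", "elevated"),
                             seed = 1L) {
  stopifnot_scalar_prob(train_frac, "train_frac")
  cells <- split(samples$id,
                 interaction(samples[, strata_cols, drop = FALSE],
                             drop = TRUE, lex.order = TRUE))
  small <- vapply(cells, length, integer(1)) < 2L
  if (any(small)) {
    warning("stratum cell(s) with < 2 samples skipped: ",
            paste(names(cells)[small], collapse = ", "))
    cells <- cells[!small]
  }
  sizes <- vapply(cells, length, integer(1))
  target <- round(train_frac * sum(sizes))
  base <- floor(train_frac * sizes)
  rem <- train_frac * sizes - base
  extra <- target - sum(base)
  alloc <- base
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem))
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
  }
  with_seed(seed, {
    train <- unlist(lapply(seq_along(cells), function(i) {
      ids <- cells[[i]]
      ids[sample.int(length(ids), alloc[i])]
    }), use.names = FALSE)
  })
  list(train = train, test = setdiff(unlist(cells, use.names = FALSE), train))
}

#' ROC evaluation of nested MRS models
#'
#' Fits nested logistic models for elevated cIMT on the training set and
#' evaluates discrimination on the test set: M1 = MRS + age + sex +
#' ethnicity; M2 = age + sex + ethnicity; M3 = M2 + smoking, emitted both
#' without (\code{m3_smoking}) and with (\code{m3_smoking_mrs}) the MRS
#' since either reading of "M2 + smoking" is defensible.  AUCs use the
#' rank statistic with ties counted half; confidence intervals and the
#' paired M1-vs-M2 difference test use DeLong's covariance method (pROC).
#'
#' @param train,test data frames with columns \code{elevated} (logical),
#'   \code{mrs}, \code{age}, \code{sex}, \code{stratum}, \code{smoking}.
#' @return list with \code{auc} (data frame: model, auc, ci_lo, ci_hi),
#'   \code{delong_m1_m2} (delta AUC and P), and the fitted \code{rocs}.
#' @export
evaluate_roc <- function(train, test) {
  if (length(unique(test$elevated)) < 2L)
    stop("test set must contain both classes", call. = FALSE)
  forms <- list(
    m1 = elevated ~ mrs + age + sex + stratum,
    m2 = elevated ~ age + sex + stratum,
    m3_smoking = elevated ~ age + sex + stratum + smoking,
    m3_smoking_mrs = elevated ~ mrs + age + sex + stratum + smoking)
  train$elevated <- as.integer(train$elevated)
  rocs <- lapply(forms, function(f) {
    fit <- glm(f, family = binomial(), data = train)
    pred <- predict(fit, newdata = test, type = "response")
    pROC::roc(response = test$elevated, predictor = pred,
              levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  })
  auc_tab <- do.call(rbind, lapply(names(rocs), function(nm) {
    ci <- pROC::ci.auc(rocs[[nm]], method = "delong")
    data.frame(model = nm, auc = as.numeric(pROC::auc(rocs[[nm]])),
               ci_lo = ci[1], ci_hi = ci[3], stringsAsFactors = FALSE)
  }))
  dl <- pROC::roc.test(rocs$m1, rocs$m2, method = "delong", paired = TRUE)
  list(auc = auc_tab,
       delong_m1_m2 = list(
         delta_auc = as.numeric(pROC::auc(rocs$m1)) -
           as.numeric(pROC::auc(rocs$m2)),
         p = dl$p.value),
       rocs = rocs)
}

#' Quartile association of the MRS with elevated cIMT
#'
#' Splits scores into quartiles (type-7 quantiles of the scored set, ties
#' assigned to the lower quartile) and fits logistic regression of
#' elevated cIMT on quartile plus covariates; odds ratios vs Q1 are the
#' exponentiated quartile coefficients with Wald 95\% intervals.  Effect
#' modification by ethnicity is assessed by a likelihood-ratio test of the
#' model with a quartile-by-ethnicity interaction against the main-effects
#' model, referred to chi-squared with the added degrees of freedom.
#'
#' @param data data frame with \code{elevated}, \code{mrs} and the
#'   covariate columns.
#' @param covariates covariate column names (default age, sex, stratum;
#'   use \code{character(0)} for an unadjusted model).
#' @return list with \code{or} (data frame: quartile, or, ci_lo, ci_hi,
#'   p), \code{interaction_lrt} (statistic, df, p), \code{quartile}
#'   (factor of assignments).
#' @export
quartile_association <- function(data, covariates = c("age", "sex", "stratum")) {
  score <- data$mrs
  if (length(unique(score[!is.na(score)])) < 4L)
    stop("need at least 4 distinct score values", call. = FALSE)
  q <- quantile(score, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  quart <- cut(score, breaks = c(-Inf, q, Inf), right = TRUE,
               labels = paste0("Q", 1:4))
  d <- data.frame(elevated = as.integer(data$elevated), quartile = quart,
                  data[, covariates, drop = FALSE])
  d <- d[complete.cases(d), , drop = FALSE]
  if (any(table(d$quartile) == 0L))
    stop("empty quartile cell after listwise deletion", call. = FALSE)
  rhs <- paste(c("quartile", covariates), collapse = " + ")
  m0 <- glm(as.formula(paste("elevated ~", rhs)), family = binomial(),
            data = d)
  cf <- summary(m0)$coefficients
  qrows <- grep("^quartileQ", rownames(cf))
  or <- data.frame(
    quartile = sub("^quartile", "", rownames(cf)[qrows]),
    or = exp(cf[qrows, 1]),
    ci_lo = exp(cf[qrows, 1] - 1.96 * cf[qrows, 2]),
    ci_hi = exp(cf[qrows, 1] + 1.96 * cf[qrows, 2]),
    p = cf[qrows, 4], row.names = NULL, stringsAsFactors = FALSE)
  lrt <- NULL
  if ("stratum" %in% covariates && length(unique(d$stratum)) > 1L) {
    m1 <- glm(as.formula(paste("elevated ~", rhs, "+ quartile:stratum")),
              family = binomial(), data = d)
    stat <- as.numeric(2 * (logLik(m1) - logLik(m0)))
    df_ <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
    lrt <- list(statistic = stat, df = df_,
                p = pchisq(stat, df_, lower.tail = FALSE))
  }
  list(or = or, interaction_lrt = lrt, quartile = quart)
}
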