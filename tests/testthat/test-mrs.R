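test_that("weight derivation Stouffer-combines per-ethnicity associations", {
  b <- tiny_bundle()
  sent <- b$truth$causal_cpgs$probe

  # single ethnicity: weight equals that stratum's z
  idx <- b$samples$stratum == "chinese"
  one <- list(methylation = list(values = b$methylation$values[idx, ]),
              samples = b$samples[idx, ])
  mod1 <- derive_weights(one, sent[1])
  f <- fit_cpg_association(log(one$samples$cimt_mean),
                           one$methylation$values[, sent[1]],
                           one$samples[, c("age", "sex")])
  expect_equal(unname(mod1$weights), f$z, tolerance = 1e-10)

  # multi-ethnic weights equal the Stouffer combination of stratum fits
  mod <- derive_weights(b, sent)
  zs <- vapply(c("chinese", "malay"), function(s) {
    i <- b$samples$stratum == s
    fit_cpg_association(log(b$samples$cimt_mean[i]),
                        b$methylation$values[i, sent[1]],
                        b$samples[i, c("age", "sex")])$z
  }, numeric(1))
  ns <- unname(table(b$samples$stratum)[c("chinese", "malay")])
  expect_equal(unname(mod$weights[sent[1]]),
               stouffer_combine(zs, as.numeric(ns))$z_meta, tolerance = 1e-10)

  # planted positive effects give positive weights
  expect_true(all(mod$weights > 0))

  # a sentinel constant within one stratum is skipped there, with a log
  b2 <- b
  b2$methylation$values[b2$samples$stratum == "malay", sent[1]] <- 0.5
  mod2 <- derive_weights(b2, sent)
  expect_match(mod2$log, "malay", all = FALSE)
  expect_true(is.finite(mod2$weights[sent[1]]))

  expect_error(derive_weights(b, "cg_nonexistent"), "absent")
})

test_that("scores are weighted sums of rank-normalised betas", {
  set.seed(20)
  B <- matrix(runif(60), 20, 3,
              dimnames = list(sprintf("S%02d", 1:20), c("c1", "c2", "c3")))
  mk <- function(w) structure(list(cpgs = colnames(B),
                                   weights = setNames(w, colnames(B))),
                              class = "mrs_model")
  expect_equal(unname(compute_mrs(mk(c(0, 0, 0)), B)), rep(0, 20))

  # k = 1, w = 1: score is the inverse-normal transform of the beta vector
  s1 <- compute_mrs(structure(list(cpgs = "c1",
                                   weights = c(c1 = 1)), class = "mrs_model"), B)
  expect_equal(unname(s1), unname(qnorm((rank(B[, 1]) - 0.5) / 20)))

  # linearity: doubling weights doubles scores
  expect_equal(compute_mrs(mk(c(2, 4, -1)), B),
               2 * compute_mrs(mk(c(1, 2, -0.5)), B), tolerance = 1e-12)

  # invariant to sample order and to per-CpG monotone transforms
  perm <- sample(20)
  expect_equal(compute_mrs(mk(c(1, 2, 3)), B[perm, ]),
               compute_mrs(mk(c(1, 2, 3)), B)[perm])
  Bt <- B; Bt[, 2] <- Bt[, 2]^3  # strictly monotone transform
  expect_equal(compute_mrs(mk(c(1, 2, 3)), Bt),
               compute_mrs(mk(c(1, 2, 3)), B))

  # missing CpG value -> missing score
  Bm <- B; Bm[3, 2] <- NA
  expect_true(is.na(compute_mrs(mk(c(1, 1, 1)), Bm)[3]))
  expect_error(compute_mrs(mk(c(1, 1, 1)), B[, 1:2]), "absent")
})

test_that("elevated classification is at-or-above the cell's 75th percentile", {
  tab <- generate_normative_table(c(30, 55, 80), c("female", "male"),
                                  "chinese",
                                  list(base = 0.6, age_slope = 0.006))
  p75 <- tab$p75[tab$age_lower == 30 & tab$sex == "female"]
  expect_true(classify_elevated(p75, 40, "female", "chinese", tab))
  expect_false(classify_elevated(p75 - 1e-9, 40, "female", "chinese", tab))
  expect_false(classify_elevated(p75, 40, "female", "chinese", tab,
                                 strict = TRUE))
  # upper boundary of the last band is supported; beyond it errors
  expect_silent(classify_elevated(0.7, 80, "male", "chinese", tab))
  expect_error(classify_elevated(0.7, 85, "male", "chinese", tab),
               "no normative reference")
})

test_that("the stratified split is proportional, disjoint and reproducible", {
  s <- data.frame(id = sprintf("S%03d", 1:100), stratum = "chinese",
                  elevated = rep(c(TRUE, FALSE), c(30, 70)))
  sp <- stratified_split(s, seed = 5)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), s$id)
  # per-cell allocation off by at most one sample from proportionality
  for (e in c(TRUE, FALSE)) {
    ids <- s$id[s$elevated == e]
    expect_lte(abs(sum(sp$train %in% ids) - 0.7 * length(ids)), 1)
  }
  expect_identical(stratified_split(s, seed = 5), sp)
  expect_false(identical(stratified_split(s, seed = 6)$train, sp$train))

  s2 <- rbind(s, data.frame(id = "S999", stratum = "malay", elevated = TRUE))
  expect_warning(stratified_split(s2, seed = 1), "skipped")
})

test_that("ROC evaluation ranks a separating score at AUC 1 and tests deltas", {
  set.seed(33)
  n <- 300
  d <- data.frame(age = runif(n, 30, 80),
                  sex = sample(c("female", "male"), n, TRUE),
                  stratum = sample(c("chinese", "malay"), n, TRUE),
                  smoking = sample(c("never", "current"), n, TRUE))
  d$mrs <- rnorm(n)
  d$elevated <- d$mrs > quantile(d$mrs, 0.75)  # perfectly separable by MRS
  train <- d[1:200, ]; test <- d[201:300, ]
  ev <- suppressWarnings(evaluate_roc(train, test))
  expect_equal(ev$auc$auc[ev$auc$model == "m1"], 1)
  expect_lt(ev$auc$auc[ev$auc$model == "m2"], 0.7)
  expect_lt(ev$delong_m1_m2$p, 0.001)
  expect_true(all(ev$auc$ci_lo <= ev$auc$auc & ev$auc$auc <= ev$auc$ci_hi))

  # in-sample: adding the MRS never reduces fit
  ev_tr <- suppressWarnings(evaluate_roc(train, train))
  expect_gte(ev_tr$auc$auc[ev_tr$auc$model == "m1"],
             ev_tr$auc$auc[ev_tr$auc$model == "m2"])

  expect_error(evaluate_roc(train, transform(test, elevated = FALSE)),
               "both classes")
})

test_that("quartile odds ratios reduce to the contingency identity", {
  # Q4: 20 elevated / 30 not; Q1: 10 / 40; OR = (20*40)/(30*10)
  d <- data.frame(
    mrs = rep(1:4, each = 50),
    elevated = c(rep(c(TRUE, FALSE), c(10, 40)),
                 rep(c(TRUE, FALSE), c(12, 38)),
                 rep(c(TRUE, FALSE), c(15, 35)),
                 rep(c(TRUE, FALSE), c(20, 30))))
  qa <- quartile_association(d, covariates = character(0))
  expect_equal(qa$or$or[qa$or$quartile == "Q4"], (20 * 40) / (30 * 10),
               tolerance = 1e-6)
  expect_equal(as.vector(table(qa$quartile)), rep(50, 4))

  expect_error(quartile_association(
    data.frame(mrs = rep(1, 10), elevated = TRUE), covariates = character(0)),
    "distinct")
})

test_that("quartile CIs cover the null and the interaction LRT is available", {
  set.seed(71)
  cover <- 0L; n_rep <- 60L
  for (r in seq_len(n_rep)) {
    n <- 400
    d <- data.frame(mrs = rnorm(n), age = runif(n, 30, 80),
                    sex = sample(c("female", "male"), n, TRUE),
                    stratum = sample(c("chinese", "malay"), n, TRUE))
    d$elevated <- runif(n) < 0.25   # independent of the score
    qa <- quartile_association(d)
    q4 <- qa$or[qa$or$quartile == "Q4", ]
    if (q4$ci_lo <= 1 && 1 <= q4$ci_hi) cover <- cover + 1L
    if (r == 1L) {
      expect_false(is.null(qa$interaction_lrt))
      expect_gte(qa$interaction_lrt$p, 0)
      expect_equal(qa$interaction_lrt$df, 3)  # (4-1) x (2-1)
    }
  }
  expect_gte(cover / n_rep, 0.93)
})
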