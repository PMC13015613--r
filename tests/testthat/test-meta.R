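test_that("Stouffer combination follows the sample-size weighted form", {
  expect_equal(stouffer_combine(2, 500)$z_meta, 2)
  expect_equal(stouffer_combine(c(1, 1), c(100, 100))$z_meta, sqrt(2),
               tolerance = 1e-12)
  s <- stouffer_combine(c(2, -2), c(100, 100))
  expect_equal(s$z_meta, 0)
  expect_equal(s$p_meta, 1)
  expect_equal(s$direction, "+-")
  # unequal n: w = sqrt(n), denominator sqrt(sum w^2)
  z <- c(1.2, -0.4, 2.1); n <- c(1063, 150, 144)
  expect_equal(stouffer_combine(z, n)$z_meta,
               sum(sqrt(n) * z) / sqrt(sum(n)), tolerance = 1e-12)
  # missing studies are dropped
  expect_equal(stouffer_combine(c(NA, 2), c(100, 100))$z_meta, 2)
  expect_equal(stouffer_combine(c(NA, NA), c(1, 1))$k, 0)
})

test_that("IVW combination matches closed forms and the WLS oracle", {
  expect_equal(ivw_combine(1.5, 0.3)$beta_meta, 1.5)
  m <- ivw_combine(c(1, 3), c(1, 1))
  expect_equal(m$beta_meta, 2)
  expect_equal(m$se_meta, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(ivw_combine(c(1, 3), c(1, 2))$beta_meta, 1.4,
               tolerance = 1e-12)
  expect_error(ivw_combine(c(1, 2), c(1, 0)), "> 0")

  # oracle: intercept-only weighted least squares with weights 1/se^2,
  # standard error rescaled to known unit residual variance
  set.seed(11)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    beta <- rnorm(k); se <- runif(k, 0.1, 2)
    fit <- lm(beta ~ 1, weights = 1 / se^2)
    sm <- summary(fit)
    m <- ivw_combine(beta, se)
    expect_equal(m$beta_meta, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(m$se_meta, sm$coefficients[1, 2] / sm$sigma,
                 tolerance = 1e-10)
  }
})

test_that("heterogeneity statistics match hand arithmetic and chi-square", {
  expect_equal(heterogeneity(c(1, 1, 1), c(0.2, 0.5, 1))$Q, 0)
  expect_equal(heterogeneity(c(1, 1, 1), c(0.2, 0.5, 1))$i2, 0)
  h <- heterogeneity(c(0, 2), c(1, 1))
  expect_equal(h$Q, 2)           # beta_IVW = 1, Q = 1 + 1
  expect_equal(h$i2, 50)         # (2 - 1)/2 * 100
  expect_true(is.na(heterogeneity(1, 1)$Q))

  # null simulation: Q ~ chi-square with k-1 df
  set.seed(5)
  Qs <- replicate(4000, {
    se <- runif(5, 0.5, 1.5)
    heterogeneity(rnorm(5, 0, se), se)$Q
  })
  expect_lt(abs(mean(Qs) - 4), 0.2)

  # I2 invariant to common rescaling of (beta, se)
  beta <- c(0.1, 0.5, -0.2); se <- c(0.2, 0.3, 0.25)
  expect_equal(heterogeneity(beta, se)$i2,
               heterogeneity(7 * beta, 7 * se)$i2, tolerance = 1e-12)
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 53466), 3), 9.35e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 3), 0.016667, tolerance = 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 10), "\\(0, 1\\)")
})

test_that("two-stage meta with one study and alpha 1 reduces to that study", {
  set.seed(3)
  study <- data.frame(probe = sprintf("cg%03d", 1:50),
                      z = rnorm(50), n = 500)
  study$p <- 2 * pnorm(-abs(study$z))
  ts <- two_stage_meta(list(study), stage1_alpha = 1)
  m <- match(study$probe, ts$stage2$probe)
  expect_equal(ts$stage2$z[m], study$z, tolerance = 1e-12)
  expect_equal(ts$availability, 1)
  expect_equal(ts$threshold, 0.05 / 50)
})

test_that("platform masks restrict stage 2 and drive the availability fraction", {
  set.seed(4)
  probes <- sprintf("cg%04d", 1:400)
  mk <- function(ids, z) data.frame(probe = ids, z = z,
                                    p = 2 * pnorm(-abs(z)), n = 300)
  z1 <- rnorm(400); z1[1:60] <- 4        # 60 clear stage-1 survivors
  asian <- list(mk(probes, z1), mk(probes, z1 + rnorm(400, 0, 0.3)))
  # the 450K-style study misses 10 of the survivors
  euro <- mk(setdiff(probes, probes[1:10]), rnorm(390))
  ts <- two_stage_meta(asian, list(euro))
  surv <- ts$survivors
  expect_true(all(probes[1:60] %in% surv))
  expect_equal(ts$availability, (length(surv) - 10) / length(surv))
  expect_equal(ts$n_stage2_tests, length(surv) - 10)
  expect_false(any(probes[1:10] %in% ts$stage2$probe))
  expect_equal(ts$threshold, 0.05 / ts$n_stage2_tests)
  # direction strings carry one character per contributing study
  expect_true(all(nchar(ts$stage2$direction) == 3))
})

test_that("an all-null two-stage design carries ~5% forward and finds no sentinels", {
  set.seed(12)
  probes <- sprintf("cg%05d", 1:20000)
  mk <- function() {
    z <- rnorm(20000)
    data.frame(probe = probes, z = z, p = 2 * pnorm(-abs(z)), n = 400)
  }
  ts <- two_stage_meta(list(mk(), mk(), mk()), list(mk()))
  frac <- length(ts$survivors) / 20000
  expect_lt(abs(frac - 0.05), 0.01)
  expect_lte(nrow(ts$sentinels), 2)  # expectation under the null is < 1
})

test_that("concordance diagnostics behave at the extremes and under noise", {
  z <- setNames(rnorm(1000), sprintf("cg%04d", 1:1000))
  same <- concordance_diagnostics(z, z)
  expect_equal(same$rho, 1)
  expect_equal(same$sign_concordance, 100)
  opp <- concordance_diagnostics(z, -z)
  expect_equal(opp$rho, -1)
  expect_equal(opp$sign_concordance, 0)
  set.seed(2)
  noisy <- concordance_diagnostics(z, z + rnorm(1000, 0, 0.1 * sd(z)))
  expect_gt(noisy$rho, 0.99)
  expect_error(concordance_diagnostics(z[1:2], z[1:2]), "at least 3")
})

test_that("discovery-specific accounting reproduces fraction arithmetic", {
  n <- 1000
  pA <- setNames(c(rep(0.01, 600), rep(0.5, 400)), sprintf("cg%04d", 1:n))
  pB <- setNames(c(rep(0.01, 150), rep(0.5, 850)), names(pA))
  r <- discovery_specific_rate(pA, pB)
  expect_equal(r$n_detected, 600)
  expect_equal(r$n_specific, 450)
  expect_equal(r$pct, 75)
})
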