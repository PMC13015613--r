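# Shared fixtures and independent oracles used across test files.

# Small cohort used by several module tests (memoised per session).
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_methylation_cohort(
        synth_config(seed = 42, strata = c(chinese = 400, malay = 120),
                     n_cpgs = 400))
    cache
  }
})

# Methylation matrix list from a bare matrix (samples x probes).
as_meth <- function(values, class = rep("CpG", ncol(values)),
                    chrom = rep("chr1", ncol(values)),
                    pos = seq_len(ncol(values)) * 1e5L) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("cg%07d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  list(values = values,
       manifest = data.frame(id = colnames(values), chrom = chrom,
                             pos = pos, class = class,
                             stringsAsFactors = FALSE))
}

# Independent colocalisation oracle: direct configuration enumeration with
# linear-scale Bayes factors (valid for small regions and moderate z).
coloc_brute <- function(a, b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        sd_prior = 0.15) {
  labf <- function(beta, se) {
    r <- sd_prior^2 / (sd_prior^2 + se^2)
    0.5 * (log(1 - r) + r * (beta / se)^2)
  }
  bfA <- exp(labf(a$beta, a$se))
  bfB <- exp(labf(b$beta, b$se))
  L <- c(H0 = 1,
         H1 = p1 * sum(bfA),
         H2 = p2 * sum(bfB),
         H3 = p1 * p2 * (sum(outer(bfA, bfB)) - sum(bfA * bfB)),
         H4 = p12 * sum(bfA * bfB))
  L / sum(L)
}

# Random small summary-statistics table for oracle checks.
random_sumstats <- function(m, z_scale = 2) {
  data.frame(variant = sprintf("v%02d", seq_len(m)),
             beta = rnorm(m, 0, 0.1 * z_scale),
             se = runif(m, 0.02, 0.1),
             p = runif(m), stringsAsFactors = FALSE)
}

# Brute-force background matcher reproducing the documented protocol
# independently: per test CpG, scan the expanding schedule over all
# candidates with a double loop, then draw with the same seeded protocol.
match_background_brute <- function(test, universe, spec) {
  universe <- universe[!(universe$id %in% test$id), , drop = FALSE]
  keep <- vapply(seq_len(nrow(universe)), function(i) {
    same <- test$chrom == universe$chrom[i]
    !any(same & abs(test$pos - universe$pos[i]) <= spec$min_distance)
  }, logical(1))
  universe <- universe[keep, , drop = FALSE]
  tol_mean <- seq(spec$mean_start, spec$mean_max, length.out = spec$steps)
  tol_sd <- seq(spec$sd_start, spec$sd_max, length.out = spec$steps)
  set.seed(spec$seed)
  sets <- matrix(NA_character_, nrow(test), spec$n_sets,
                 dimnames = list(test$id, NULL))
  achieved <- rep(NA_integer_, nrow(test))
  for (i in seq_len(nrow(test))) {
    for (k in seq_len(spec$steps)) {
      ok <- logical(nrow(universe))
      for (j in seq_len(nrow(universe)))
        ok[j] <- abs(universe$mean[j] - test$mean[i]) <= tol_mean[k] &&
          abs(universe$sd[j] - test$sd[i]) <= tol_sd[k]
      if (sum(ok) >= spec$n_sets) {
        ids <- universe$id[ok]
        sets[i, ] <- ids[sample.int(length(ids), spec$n_sets)]
        achieved[i] <- k
        break
      }
    }
  }
  list(sets = sets, achieved_step = achieved)
}
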