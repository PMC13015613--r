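test_that("matching specs validate their schedules", {
  expect_error(match_spec(n_sets = 0), "n_sets")
  expect_error(match_spec(mean_start = 0.3, mean_max = 0.25), "expanding")
})

test_that("exact duplicates match at the first step; small universes fail", {
  test <- data.frame(id = "t1", chrom = "chr1", pos = 1e6,
                     mean = 0.5, sd = 0.05)
  dup <- data.frame(id = sprintf("u%03d", 1:250), chrom = "chr2",
                    pos = seq_len(250) * 1e4, mean = 0.5, sd = 0.05)
  bg <- match_background(test, dup, match_spec(n_sets = 200, seed = 1))
  expect_equal(bg$achieved_step, 1L)
  expect_equal(ncol(bg$sets), 200)
  expect_equal(anyDuplicated(bg$sets[1, ]), 0)  # no reuse within a test CpG

  expect_error(match_background(test, dup[1:100, ],
                                match_spec(n_sets = 200, seed = 1)),
               "unmatched.*t1")
})

test_that("the distance rule excludes candidates near any test CpG", {
  test <- data.frame(id = c("t1", "t2"), chrom = "chr1",
                     pos = c(1e6, 2e6), mean = 0.5, sd = 0.05)
  uni <- data.frame(
    id = c("near_t1", "near_t2", "far", sprintf("u%03d", 1:40)),
    chrom = "chr1",
    pos = c(1e6 + 4000, 2e6 - 3000, 3e6, 5e6 + seq_len(40) * 1e5),
    mean = 0.5, sd = 0.05)
  bg <- match_background(test, uni, match_spec(n_sets = 10, seed = 2))
  expect_false(any(c("near_t1", "near_t2") %in% bg$sets))
  expect_true(all(bg$sets %in% setdiff(uni$id, c("near_t1", "near_t2"))))
})

test_that("tolerance expansion stops at the first sufficient step", {
  # 5 candidates inside the tight band, 300 only in a wider band: with
  # n_sets = 50 the matcher must expand until the wider band qualifies.
  test <- data.frame(id = "t1", chrom = "chr1", pos = 1e6,
                     mean = 0.5, sd = 0.01)
  uni <- rbind(
    data.frame(id = sprintf("tight%02d", 1:5), chrom = "chr2",
               pos = seq_len(5) * 1e4, mean = 0.5, sd = 0.01),
    data.frame(id = sprintf("wide%03d", 1:300), chrom = "chr2",
               pos = 1e6 + seq_len(300) * 1e4, mean = 0.62, sd = 0.018))
  spec <- match_spec(n_sets = 50, seed = 3)
  bg <- match_background(test, uni, spec)
  # |0.62 - 0.5| = 0.12 first within tolerance at step ceil: schedule is
  # seq(0.025, 0.25, length.out = 10); 0.12 <= tol from step 5 (0.125);
  # sd diff 0.008 <= tol from step 3 (0.0075? no: seq(0.0025,0.025)[3]=0.0075)
  sd_sched <- seq(0.0025, 0.025, length.out = 10)
  mean_sched <- seq(0.025, 0.25, length.out = 10)
  k_expect <- which(mean_sched >= 0.12 & sd_sched >= 0.008)[1]
  expect_equal(bg$achieved_step, k_expect)
})

test_that("matching equals the brute-force schedule scan and is deterministic", {
  set.seed(14)
  uni <- data.frame(id = sprintf("u%04d", 1:3000),
                    chrom = sample(paste0("chr", 1:5), 3000, TRUE),
                    pos = sample.int(5e7, 3000),
                    mean = runif(3000), sd = runif(3000, 0.005, 0.06))
  test <- uni[sample.int(3000, 4), ]
  test$mean <- pmin(pmax(test$mean + rnorm(4, 0, 0.01), 0), 1)
  spec <- match_spec(n_sets = 25, seed = 99)
  got <- match_background(test, uni, spec)
  want <- match_background_brute(test, uni, spec)
  expect_identical(got$sets, want$sets)
  expect_identical(got$achieved_step, want$achieved_step)
  # determinism under the seed
  expect_identical(got$sets, match_background(test, uni, spec)$sets)
})

test_that("empirical enrichment arithmetic matches the counting rule", {
  bg <- structure(list(sets = matrix(sprintf("u%03d", 1:200), 1, 200,
                                     dimnames = list("t1", NULL))),
                  class = "background_sets")
  eqtm <- data.frame(probe = c("t1", sprintf("u%03d", 1:200)),
                     gene = c("G1", sprintf("bg%03d", 1:200)),
                     p = 1e-6)
  # test maps to G1; no background set reaches overlap 1
  res <- overlap_enrichment("t1", bg, list(TERM = "G1"), mode = "geneset",
                            eqtm = eqtm)
  expect_equal(res$test_overlap, 1)
  expect_equal(res$p_empirical, 0)
  expect_true(res$significant)

  # 10 of 200 sets tie or exceed -> p = 0.05, not significant
  eqtm2 <- eqtm
  eqtm2$gene[2:11] <- "G1"  # u001..u010 also map to G1
  res2 <- overlap_enrichment("t1", bg, list(TERM = "G1"), mode = "geneset",
                             eqtm = eqtm2)
  expect_equal(res2$p_empirical, 0.05)
  expect_false(res2$significant)

  # fold change = test / background mean
  expect_equal(res2$fold_change, 1 / mean(c(rep(1, 10), rep(0, 190))))

  # empirical p invariant to background set ordering
  bgp <- bg; bgp$sets <- bgp$sets[, sample(200), drop = FALSE]
  expect_equal(overlap_enrichment("t1", bgp, list(TERM = "G1"),
                                  mode = "geneset", eqtm = eqtm2)$p_empirical,
               res2$p_empirical)

  expect_error(overlap_enrichment("t1", bg, list(TERM = "G1"),
                                  mode = "geneset"), "eQTM")
})

test_that("TFBS overlap respects 0-based half-open interval semantics", {
  bg <- structure(list(sets = matrix(c("u1", "u2"), 1, 2,
                                     dimnames = list("t1", NULL))),
                  class = "background_sets")
  positions <- data.frame(id = c("t1", "u1", "u2"), chrom = "chr1",
                          pos = c(100, 500, 600))
  # interval [99, 100) covers 1-based position 100 only
  bed <- data.frame(chrom = "chr1", start = 99, end = 100, name = "TF1")
  res <- overlap_enrichment("t1", bg, bed, mode = "tfbs",
                            positions = positions)
  expect_equal(res$test_overlap, 1)
  expect_equal(res$bg_mean, 0)
  # interval [100, 101) covers position 101, not 100
  bed2 <- data.frame(chrom = "chr1", start = 100, end = 101, name = "TF1")
  res2 <- overlap_enrichment("t1", bg, bed2, mode = "tfbs",
                             positions = positions)
  expect_equal(res2$test_overlap, 0)
})

test_that("the end-to-end enrichment pipeline flags the planted annotation", {
  b <- generate_methylation_cohort(
    synth_config(seed = 19, strata = c(chinese = 500), n_cpgs = 3000))
  e <- run_stratified_ewas(b, covariates = c("age", "sex"))
  studies <- split(e[, c("probe", "z", "p", "n")], e$stratum)
  ts <- two_stage_meta(studies)
  ann <- generate_annotation_fixtures(b)
  uni <- cpg_summary(b$methylation)
  res <- run_enrichment(ts$stage1, uni, gene_sets = ann$gene_sets,
                        tfbs = ann$tfbs, eqtm = ann$eqtm,
                        spec = match_spec(n_sets = 100, seed = 7))
  expect_true(all(b$truth$causal_cpgs$probe %in% res$test_cpgs))
  gs <- res$gene_sets[res$gene_sets$term == "PLANTED_SET", ]
  expect_equal(gs$p_empirical, 0)
  expect_true(gs$significant)
  tf <- res$tfbs[res$tfbs$term == "TF_PLANTED", ]
  expect_equal(tf$p_empirical, 0)
  expect_gte(tf$fold_change, 1)

  # nothing below the suggestive threshold -> empty, successful report
  null_assoc <- data.frame(probe = uni$id, p = 0.5)
  empty <- run_enrichment(null_assoc, uni, gene_sets = ann$gene_sets,
                          eqtm = ann$eqtm)
  expect_length(empty$test_cpgs, 0)
  expect_equal(nrow(empty$gene_sets), 0)
})
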