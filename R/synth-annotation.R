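# Normative-table and annotation-fixture generators.

#' Generate a normative cIMT percentile table
#'
#' Builds an age-band x sex x ethnicity table of 75th-percentile cIMT
#' values (mm) from a multiplicative log-scale model:
#' \code{p75 = base * exp(age_slope * (midpoint - 50) + sex + ethnicity)}.
#' With a positive \code{age_slope} the 75th percentile is strictly
#' increasing across age bands within every sex x ethnicity cell, mirroring
#' published normative ranges.
#'
#' @param age_breaks increasing numeric vector of band boundaries
#'   (years); band \code{i} covers \code{[age_breaks[i], age_breaks[i+1])},
#'   the last band including its upper boundary.  Must not extend beyond
#'   80 years (older ages have no normative reference).
#' @param sexes,ethnicities character vectors of levels.
#' @param percentile_params list with \code{base} (mm, reference cell at
#'   age 50), \code{age_slope} (per year, log scale), \code{sex_effects}
#'   and \code{ethnicity_effects} (named numeric, log scale; missing levels
#'   default to 0).
#' @return a data frame of class \code{normative_table} with columns
#'   \code{age_lower, age_upper, sex, ethnicity, p75}.
#' @examples
#' tab <- generate_normative_table(c(30, 55, 80), "female", "chinese",
#'   list(base = 0.6, age_slope = 0.005))
#' tab
#' @export
generate_normative_table <- function(age_breaks = c(30, 40, 50, 60, 70, 80),
                                     sexes = c("female", "male"),
                                     ethnicities = c("chinese", "malay", "indian"),
                                     percentile_params = list()) {
  if (length(age_breaks) < 2L || any(diff(age_breaks) <= 0))
    stop("age_breaks must be strictly increasing with >= 2 values",
         call. = FALSE)
  if (max(age_breaks) > 80)
    stop("normative bands must not extend beyond 80 years", call. = FALSE)
  pp <- percentile_params
  base <- if (is.null(pp$base)) 0.62 else pp$base
  age_slope <- if (is.null(pp$age_slope)) 0.006 else pp$age_slope
  sex_eff <- pp$sex_effects
  eth_eff <- pp$ethnicity_effects
  nb <- length(age_breaks) - 1L
  grid <- expand.grid(band = seq_len(nb), sex = sexes,
                      ethnicity = ethnicities, stringsAsFactors = FALSE)
  mid <- (age_breaks[grid$band] + age_breaks[grid$band + 1L]) / 2
  eff <- function(v, lev) if (is.null(v) || is.na(match(lev, names(v)))) 0 else v[[lev]]
  lp <- age_slope * (mid - 50) +
    vapply(grid$sex, eff, numeric(1), v = sex_eff) +
    vapply(grid$ethnicity, eff, numeric(1), v = eth_eff)
  out <- data.frame(age_lower = age_breaks[grid$band],
                    age_upper = age_breaks[grid$band + 1L],
                    sex = grid$sex, ethnicity = grid$ethnicity,
                    p75 = base * exp(lp), stringsAsFactors = FALSE)
  class(out) <- c("normative_table", "data.frame")
  out
}

#' Calibrate normative-table parameters from a cohort
#'
#' Fits \code{log(cIMT) ~ age + sex + ethnicity} in a reference cohort and
#' returns \code{percentile_params} for [generate_normative_table()] whose
#' implied 75th percentiles match the cohort's covariate-adjusted cIMT
#' distribution (residual 75th percentile added on the log scale).
#'
#' @param samples data frame with \code{age}, \code{sex}, \code{stratum}
#'   (ethnicity) and \code{cimt_mean} columns, e.g. the \code{samples}
#'   element of a [generate_methylation_cohort()] bundle.
#' @return a \code{percentile_params} list.
#' @export
calibrate_normative_params <- function(samples) {
  fit <- lm(log(cimt_mean) ~ age + sex + stratum, data = samples)
  cf <- coef(fit)
  q75 <- quantile(residuals(fit), 0.75, names = FALSE, type = 7)
  sex_levels <- sort(unique(samples$sex))
  eth_levels <- sort(unique(samples$stratum))
  getco <- function(prefix, lev)
    if (paste0(prefix, lev) %in% names(cf)) unname(cf[paste0(prefix, lev)]) else 0
  list(base = exp(cf[["(Intercept)"]] + 50 * cf[["age"]] + q75),
       age_slope = cf[["age"]],
       sex_effects = setNames(vapply(sex_levels, getco, numeric(1),
                                     prefix = "sex"), sex_levels),
       ethnicity_effects = setNames(vapply(eth_levels, getco, numeric(1),
                                           prefix = "stratum"), eth_levels))
}

#' Generate gene-set, TFBS and eQTM annotation fixtures
#'
#' Builds the annotation inputs of the enrichment stage with planted truth:
#' a GMT gene-set collection containing one term (\code{PLANTED_SET})
#' covering the genes cis-mapped to the bundle's causal CpGs plus random
#' terms; a BED collection of transcription-factor binding intervals with
#' one factor (\code{TF_PLANTED}) covering every causal CpG position plus
#' random factors; and a CpG-to-gene eQTM mapping table in which planted
#' pairs carry strong support and all other pairs a null (uniform) P.
#'
#' @param bundle a \code{cohort_bundle}.
#' @param out_dir optional directory; if supplied, writes
#'   \code{genesets.gmt}, \code{tfbs.bed} (0-based half-open) and
#'   \code{eqtm_map.tsv} there.
#' @param n_random_terms,n_random_tfs numbers of random gene sets and
#'   random TF interval tracks to add around the planted ones.
#' @param interval_halfwidth half-width (bp) of TFBS intervals.
#' @return list with \code{gene_sets} (named list), \code{tfbs} (data frame
#'   \code{chrom, start, end, name}, 0-based half-open), \code{eqtm}
#'   (data frame \code{probe, gene, beta, p}), and \code{paths} (written
#'   files, if any).
#' @export
generate_annotation_fixtures <- function(bundle, out_dir = NULL,
                                         n_random_terms = 10L,
                                         n_random_tfs = 8L,
                                         interval_halfwidth = 100L) {
  if (!inherits(bundle, "cohort_bundle"))
    stop("'bundle' must be a cohort_bundle", call. = FALSE)
  config <- bundle$config
  with_seed(config$seed + 104729L, {
    probes <- bundle$methylation$manifest
    genes <- bundle$expression$manifest
    planted_eqtm <- bundle$truth$eqtm

    # eQTM map: every CpG paired with a random gene (null P); planted pairs
    # get strong support.
    eqtm <- data.frame(
      probe = probes$id,
      gene = sample(genes$id, nrow(probes), replace = TRUE),
      beta = rnorm(nrow(probes), 0, 0.1),
      p = runif(nrow(probes)), stringsAsFactors = FALSE)
    if (!is.null(planted_eqtm) && nrow(planted_eqtm)) {
      keep <- !(eqtm$probe %in% planted_eqtm$probe)
      eqtm <- rbind(eqtm[keep, ],
                    data.frame(probe = planted_eqtm$probe,
                               gene = planted_eqtm$gene,
                               beta = planted_eqtm$effect,
                               p = 1e-8, stringsAsFactors = FALSE))
    }

    gene_sets <- list()
    if (!is.null(planted_eqtm) && nrow(planted_eqtm))
      gene_sets$PLANTED_SET <- unique(planted_eqtm$gene)
    if (n_random_terms > 0L) {
      rnd <- lapply(seq_len(n_random_terms), function(i)
        sample(genes$id, min(nrow(genes), sample(3:8, 1L))))
      names(rnd) <- sprintf("RANDOM_SET_%02d", seq_len(n_random_terms))
      gene_sets <- c(gene_sets, rnd)
    }

    tfbs <- NULL
    causal <- bundle$truth$causal_cpgs$probe
    if (length(causal)) {
      idx <- match(causal, probes$id)
      tfbs <- data.frame(chrom = probes$chrom[idx],
                         start = pmax(0L, probes$pos[idx] - 1L - interval_halfwidth),
                         end = probes$pos[idx] + interval_halfwidth,
                         name = "TF_PLANTED", stringsAsFactors = FALSE)
    }
    if (n_random_tfs > 0L) {
      k <- 5L
      rnd_tf <- do.call(rbind, lapply(seq_len(n_random_tfs), function(i) {
        j <- sample.int(nrow(probes), k)
        data.frame(chrom = probes$chrom[j],
                   start = pmax(0L, probes$pos[j] - 1L - interval_halfwidth +
                                  sample(c(-5000L, 5000L), k, TRUE)),
                   end = probes$pos[j] + interval_halfwidth +
                     sample(c(-5000L, 5000L), k, TRUE),
                   name = sprintf("TF_RANDOM_%02d", i),
                   stringsAsFactors = FALSE)
      }))
      rnd_tf <- rnd_tf[rnd_tf$end > rnd_tf$start, ]
      tfbs <- rbind(tfbs, rnd_tf)
    }

    paths <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(
        write_gmt(gene_sets, file.path(out_dir, "genesets.gmt")),
        if (!is.null(tfbs)) write_bed(tfbs, file.path(out_dir, "tfbs.bed")),
        {
          p <- file.path(out_dir, "eqtm_map.tsv")
          write.table(eqtm, p, sep = "\t", quote = FALSE, row.names = FALSE)
          p
        })
    }
    list(gene_sets = gene_sets, tfbs = tfbs, eqtm = eqtm, paths = paths)
  })
}
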