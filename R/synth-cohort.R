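#' Generate a multi-ethnic methylation cohort with planted truth
#'
#' Simulates a cohort with the statistical structure an EWAS of cIMT
#' assumes: strata of differing size sharing causal CpGs, methylation beta
#' values with logit-normal (0,1) support, log-normally distributed cIMT
#' driven by age, sex, smoking and the planted CpG effects, and cis genetic
#' control of methylation and expression (meQTL/eQTL/eQTM triplets).
#'
#' The outcome model is
#' \deqn{\ln(cIMT) = \alpha + a\,(age-50) + s\,[male] + smoking +
#'   \sum_j \gamma_j (\beta_j - 0.5) + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma^2)}
#' with \eqn{\gamma_j} equal to \code{causal_effect} times the stratum
#' multiplier at planted CpGs and 0 elsewhere.  Centring betas at 0.5 keeps
#' the intercept interpretable as a typical cIMT (about 0.55 mm at age 50).
#'
#' @param config a [synth_config()] object.
#' @return an object of class \code{cohort_bundle}: a list with elements
#'   \code{methylation} (list: \code{values} samples x probes matrix in
#'   (0,1), \code{manifest} probe data frame, \code{platform}),
#'   \code{samples} (data frame: id, stratum, age, sex, smoking, six cell
#'   proportions summing to 1, technical PCs, \code{cimt_mean} in mm),
#'   \code{genotypes} (list: \code{dosage} samples x variants in [0,2],
#'   \code{manifest}), \code{expression} (list: \code{values} genes x
#'   samples, \code{manifest}), \code{truth} (planted causal CpGs and
#'   QTL/QTM triplets with their effects), and \code{config}.
#' @examples
#' bundle <- generate_methylation_cohort(
#'   synth_config(seed = 7, strata = c(chinese = 120, malay = 60),
#'                n_cpgs = 200))
#' str(bundle$truth$causal_cpgs)
#' @export
generate_methylation_cohort <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("'config' must be a synth_config object", call. = FALSE)
  if (any(config$strata <= 0L))
    stop("every stratum must have at least one sample", call. = FALSE)
  with_seed(config$seed, {
    strata <- config$strata
    n <- sum(strata)
    p <- config$n_cpgs
    stratum <- rep(names(strata), strata)
    sample_id <- sprintf("S%05d", seq_len(n))

    age <- round(runif(n, 30, 80))
    sex <- sample(c("female", "male"), n, replace = TRUE)
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.60, 0.25, 0.15))
    # Houseman-style leukocyte proportions (Dirichlet, granulocyte-dominant)
    cell_types <- c("cd4t", "cd8t", "bcell", "nk", "mono", "gran")
    alphas <- c(4, 2.5, 1.5, 1.5, 2, 12)
    cells <- matrix(rgamma(n * 6L, shape = rep(alphas, each = n)), n, 6L)
    cells <- cells / rowSums(cells)
    colnames(cells) <- cell_types
    pcs <- matrix(rnorm(n * 5L), n, 5L,
                  dimnames = list(NULL, paste0("pc", 1:5)))

    samples <- data.frame(id = sample_id, stratum = stratum, age = age,
                          sex = sex, smoking = smoking,
                          cells, pcs,
                          stringsAsFactors = FALSE)

    probe_id <- sprintf("cg%07d", seq_len(p))
    probe_chrom <- sample(paste0("chr", 1:22), p, replace = TRUE)
    probe_pos <- sample.int(2.4e8, p, replace = TRUE)
    manifest <- data.frame(id = probe_id, chrom = probe_chrom,
                           pos = probe_pos, class = "CpG",
                           stringsAsFactors = FALSE)

    mu <- rnorm(p, 0, config$logit_mean_sd)
    causal_idx <- if (config$n_causal_cpgs > 0L)
      sort(sample.int(p, config$n_causal_cpgs)) else integer(0)
    # causal CpGs are drawn from the variable, intermediate-methylation part
    # of the array (association signals require between-sample variability)
    if (length(causal_idx))
      mu[causal_idx] <- rnorm(length(causal_idx), 0, 0.5)
    L <- matrix(rnorm(n * p, 0, config$logit_sd), n, p)
    L <- sweep(L, 2L, mu, "+")

    # genotypes: independent variants; planted variants placed cis to their CpG
    v <- config$n_variants
    maf <- runif(v, config$maf_range[1], config$maf_range[2])
    dosage <- matrix(rbinom(n * v, 2L, rep(maf, each = n)), n, v)
    variant_id <- sprintf("rs%06d", seq_len(v))
    var_chrom <- sample(paste0("chr", 1:22), v, replace = TRUE)
    var_pos <- sample.int(2.4e8, v, replace = TRUE)

    g <- config$n_genes
    gene_id <- sprintf("GENE%03d", seq_len(g))
    gene_chrom <- sample(paste0("chr", 1:22), g, replace = TRUE)
    gene_tss <- sample.int(2.4e8, g, replace = TRUE)

    k_t <- min(length(causal_idx), v, g)
    triplets <- NULL
    if (k_t > 0L) {
      t_cpg <- causal_idx[seq_len(k_t)]
      t_var <- seq_len(k_t)
      t_gene <- seq_len(k_t)
      var_chrom[t_var] <- probe_chrom[t_cpg]
      var_pos[t_var] <- probe_pos[t_cpg] + 5e4L
      gene_chrom[t_gene] <- probe_chrom[t_cpg]
      gene_tss[t_gene] <- pmax(1L, probe_pos[t_cpg] - 2e5L)
      for (i in seq_len(k_t))
        L[, t_cpg[i]] <- L[, t_cpg[i]] + config$meqtl_effect * dosage[, t_var[i]]
      triplets <- list(cpg = t_cpg, var = t_var, gene = t_gene)
    }

    beta <- 1 / (1 + exp(-L))
    rm(L)
    dimnames(beta) <- list(sample_id, probe_id)
    dimnames(dosage) <- list(sample_id, variant_id)

    mult <- config$stratum_effect_multipliers[stratum]
    meth_term <- 0
    if (length(causal_idx))
      meth_term <- (beta[, causal_idx, drop = FALSE] - 0.5) %*%
        rep(config$causal_effect, length(causal_idx)) * mult
    ln_cimt <- log(0.55) + 0.006 * (age - 50) + 0.04 * (sex == "male") +
      0.03 * (smoking == "current") + 0.01 * (smoking == "former") +
      as.vector(meth_term) + rnorm(n, 0, config$noise_sd)
    samples$cimt_mean <- exp(ln_cimt)

    expr <- matrix(rnorm(n * g), n, g, dimnames = list(sample_id, gene_id))
    if (!is.null(triplets)) {
      for (i in seq_along(triplets$cpg)) {
        expr[, triplets$gene[i]] <- expr[, triplets$gene[i]] +
          config$eqtl_effect * dosage[, triplets$var[i]] +
          config$eqtm_effect * (beta[, triplets$cpg[i]] - 0.5)
      }
    }

    truth <- list(
      causal_cpgs = data.frame(
        probe = probe_id[causal_idx],
        effect = rep(config$causal_effect, length(causal_idx)),
        stringsAsFactors = FALSE),
      stratum_effect_multipliers = config$stratum_effect_multipliers,
      meqtl = if (is.null(triplets)) NULL else data.frame(
        variant = variant_id[triplets$var], probe = probe_id[triplets$cpg],
        effect_logit = config$meqtl_effect, stringsAsFactors = FALSE),
      eqtl = if (is.null(triplets)) NULL else data.frame(
        variant = variant_id[triplets$var], gene = gene_id[triplets$gene],
        effect = config$eqtl_effect, stringsAsFactors = FALSE),
      eqtm = if (is.null(triplets)) NULL else data.frame(
        probe = probe_id[triplets$cpg], gene = gene_id[triplets$gene],
        effect = config$eqtm_effect, stringsAsFactors = FALSE))

    structure(list(
      methylation = list(values = beta, manifest = manifest,
                         platform = "EPIC"),
      samples = samples,
      genotypes = list(dosage = dosage,
                       manifest = data.frame(id = variant_id,
                                             chrom = var_chrom, pos = var_pos,
                                             ea = "A", oa = "G", maf = maf,
                                             stringsAsFactors = FALSE)),
      expression = list(values = t(expr),
                        manifest = data.frame(id = gene_id,
                                              chrom = gene_chrom,
                                              tss = gene_tss,
                                              stringsAsFactors = FALSE)),
      truth = truth,
      config = config
    ), class = "cohort_bundle")
  })
}

#' Write a cohort bundle as tab-delimited tables
#'
#' Serialises every component of a [generate_methylation_cohort()] bundle to
#' plain tab-delimited files with header rows (methylation, samples, dosage,
#' expression, plus probe/variant/gene manifests).
#'
#' @param bundle a \code{cohort_bundle}.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "cohort_bundle"))
    stop("'bundle' must be a cohort_bundle", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    path <- file.path(dir, f)
    write.table(x, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    path
  }
  files <- c(
    wt(data.frame(id = rownames(bundle$methylation$values),
                  bundle$methylation$values, check.names = FALSE),
       "methylation.tsv"),
    wt(bundle$methylation$manifest, "probes.tsv"),
    wt(bundle$samples, "samples.tsv"),
    wt(data.frame(id = rownames(bundle$genotypes$dosage),
                  bundle$genotypes$dosage, check.names = FALSE),
       "dosage.tsv"),
    wt(bundle$genotypes$manifest, "variants.tsv"),
    wt(data.frame(id = rownames(bundle$expression$values),
                  bundle$expression$values, check.names = FALSE),
       "expression.tsv"),
    wt(bundle$expression$manifest, "genes.tsv"))
  invisible(files)
}
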