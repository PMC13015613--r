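# Methylation-matched background construction and permutation enrichment.

#' Matching specification for background construction
#'
#' Tolerances expand in lockstep over \code{steps} evenly spaced stages,
#' from \code{mean_start}/\code{sd_start} to \code{mean_max}/\code{sd_max},
#' until \code{n_sets} candidates are found for each test CpG.
#'
#' @param n_sets number of matched background sets (default 200).
#' @param mean_start,mean_max mean-methylation tolerance schedule
#'   (default +/-0.025 to +/-0.25).
#' @param sd_start,sd_max SD tolerance schedule (default +/-0.0025 to
#'   +/-0.025).
#' @param min_distance minimum distance (bp) of a background CpG from every
#'   test CpG (default 5000).
#' @param steps number of schedule stages (default 10).
#' @param seed RNG seed for the without-replacement draws.
#' @return a \code{match_spec} list.
#' @export
match_spec <- function(n_sets = 200L, mean_start = 0.025, mean_max = 0.25,
                       sd_start = 0.0025, sd_max = 0.025,
                       min_distance = 5000L, steps = 10L, seed = 1L) {
  if (n_sets < 1L) stop("n_sets must be >= 1", call. = FALSE)
  if (mean_max <= mean_start || sd_max <= sd_start)
    stop("tolerance schedules must be strictly expanding", call. = FALSE)
  structure(list(n_sets = as.integer(n_sets), mean_start = mean_start,
                 mean_max = mean_max, sd_start = sd_start, sd_max = sd_max,
                 min_distance = as.integer(min_distance),
                 steps = as.integer(steps), seed = as.integer(seed)),
            class = "match_spec")
}

#' Per-CpG summary statistics for matching
#'
#' Mean and SD of methylation beta per probe, joined with manifest
#' coordinates -- the matching universe for [match_background()].
#'
#' @param methylation methylation matrix list (\code{values} samples x
#'   probes, \code{manifest}).
#' @return data frame: \code{id, chrom, pos, mean, sd}.
#' @export
cpg_summary <- function(methylation) {
  vals <- methylation$values
  man <- methylation$manifest
  m <- match(colnames(vals), man$id)
  data.frame(id = colnames(vals), chrom = man$chrom[m], pos = man$pos[m],
             mean = colMeans(vals, na.rm = TRUE),
             sd = apply(vals, 2L, sd, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Distance (bp) from each universe CpG to the nearest test CpG on the same
# chromosome (Inf when no test CpG shares the chromosome).
min_distance_to_test <- function(universe, test) {
  out <- rep(Inf, nrow(universe))
  for (ch in unique(test$chrom)) {
    tp <- sort(test$pos[test$chrom == ch])
    ui <- which(universe$chrom == ch)
    if (!length(ui)) next
    up <- universe$pos[ui]
    k <- findInterval(up, tp)
    lo <- ifelse(k >= 1L, up - tp[pmax(k, 1L)], Inf)
    hi <- ifelse(k < length(tp), tp[pmin(k + 1L, length(tp))] - up, Inf)
    out[ui] <- pmin(abs(lo), abs(hi))
  }
  out
}

#' Adaptive methylation-matched background selection
#'
#' For each test CpG, selects \code{n_sets} background CpGs matched on mean
#' and SD of methylation.  Candidates are first restricted to CpGs more
#' than \code{min_distance} bp from every test CpG (addressing array
#' sampling bias near the association signals), then accepted when both
#' |mean difference| and |SD difference| fall within the current tolerance;
#' tolerances expand stage by stage until at least \code{n_sets} candidates
#' qualify, at which point \code{n_sets} are drawn without replacement
#' (seeded) and assigned to sets in draw order.  A test CpG that cannot be
#' matched at the maximum tolerance raises an error naming the offenders.
#'
#' @param test data frame of test CpGs: \code{id, chrom, pos, mean, sd}.
#' @param universe data frame of candidate CpGs with the same columns
#'   (test CpGs are excluded automatically).
#' @param spec a [match_spec()].
#' @return list of class \code{background_sets}: \code{sets} (matrix of
#'   CpG ids, one row per test CpG, one column per background set),
#'   \code{achieved_step} (schedule stage at which each test CpG matched),
#'   \code{spec}.
#' @export
match_background <- function(test, universe, spec = match_spec()) {
  universe <- universe[!(universe$id %in% test$id), , drop = FALSE]
  dist_ok <- min_distance_to_test(universe, test) > spec$min_distance
  universe <- universe[dist_ok, , drop = FALSE]
  tol_mean <- seq(spec$mean_start, spec$mean_max, length.out = spec$steps)
  tol_sd <- seq(spec$sd_start, spec$sd_max, length.out = spec$steps)
  with_seed(spec$seed, {
    sets <- matrix(NA_character_, nrow(test), spec$n_sets,
                   dimnames = list(test$id, NULL))
    achieved <- rep(NA_integer_, nrow(test))
    unmatched <- character(0)
    for (i in seq_len(nrow(test))) {
      dm <- abs(universe$mean - test$mean[i])
      ds <- abs(universe$sd - test$sd[i])
      for (k in seq_len(spec$steps)) {
        ok <- dm <= tol_mean[k] & ds <= tol_sd[k]
        if (sum(ok) >= spec$n_sets) {
          ids <- universe$id[ok]
          sets[i, ] <- ids[sample.int(length(ids), spec$n_sets)]
          achieved[i] <- k
          break
        }
      }
      if (is.na(achieved[i])) unmatched <- c(unmatched, test$id[i])
    }
    if (length(unmatched))
      stop("unmatched test CpG(s) at maximum tolerance: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    structure(list(sets = sets, achieved_step = achieved, spec = spec),
              class = "background_sets")
  })
}

# CpGs (1-based positions) overlapping any interval of a 0-based half-open
# BED data frame.
cpgs_in_intervals <- function(cpgs, bed) {
  if (!nrow(bed)) return(rep(FALSE, nrow(cpgs)))
  lev <- union(unique(cpgs$chrom), unique(bed$chrom))
  gr_cpg <- GenomicRanges::GRanges(factor(cpgs$chrom, lev),
                                   IRanges::IRanges(cpgs$pos, cpgs$pos))
  gr_bed <- GenomicRanges::GRanges(factor(bed$chrom, lev),
                                   IRanges::IRanges(bed$start + 1L, bed$end))
  GenomicRanges::countOverlaps(gr_cpg, gr_bed) > 0L
}

#' Permutation enrichment of test CpGs against matched backgrounds
#'
#' For each annotation term, compares the test-set overlap with the
#' overlap of each matched background set.  In gene-set mode, CpGs are
#' first mapped to genes through the supplied eQTM table restricted to
#' pairs with cis-eQTM support (\code{p < eqtm_p_max}) and distinct genes
#' are counted; in TFBS mode, CpGs whose position falls inside any of the
#' factor's BED intervals are counted.  The empirical P is the fraction of
#' background sets whose overlap equals or exceeds the test overlap, so
#' ties count against the test set; a term is significant below
#' \code{alpha} (0.005: no qualifying set out of 200).
#'
#' @param test_ids character vector of test CpG ids.
#' @param backgrounds a \code{background_sets} from [match_background()].
#' @param terms gene-set mode: named list of gene vectors (e.g. from
#'   [read_gmt()]); TFBS mode: BED data frame (\code{chrom, start, end,
#'   name}, 0-based half-open) whose \code{name} labels the factor.
#' @param mode \code{"geneset"} or \code{"tfbs"}.
#' @param eqtm CpG-gene mapping data frame (\code{probe, gene, p});
#'   required in gene-set mode.
#' @param positions CpG coordinates data frame (\code{id, chrom, pos});
#'   required in TFBS mode.
#' @param eqtm_p_max cis-eQTM support threshold (default 0.05).
#' @param alpha empirical significance threshold (default 0.005).
#' @return data frame with one row per term: \code{term, test_overlap,
#'   bg_mean, fold_change, p_empirical, significant}.
#' @export
overlap_enrichment <- function(test_ids, backgrounds, terms,
                               mode = c("geneset", "tfbs"), eqtm = NULL,
                               positions = NULL, eqtm_p_max = 0.05,
                               alpha = 0.005) {
  mode <- match.arg(mode)
  sets <- backgrounds$sets
  n_sets <- ncol(sets)
  if (mode == "geneset") {
    if (is.null(eqtm))
      stop("gene-set mode requires a CpG-to-gene eQTM mapping", call. = FALSE)
    map <- eqtm[!is.na(eqtm$p) & eqtm$p < eqtm_p_max, c("probe", "gene")]
    genes_of <- function(ids) unique(map$gene[map$probe %in% ids])
    test_feat <- genes_of(test_ids)
    bg_feat <- lapply(seq_len(n_sets), function(j) genes_of(sets[, j]))
    term_list <- terms
    count <- function(feat, members) length(intersect(feat, members))
  } else {
    if (is.null(positions))
      stop("TFBS mode requires CpG positions", call. = FALSE)
    if (!nrow(terms)) return(empty_enrichment())
    term_list <- split(terms, terms$name)
    pos_of <- function(ids) positions[match(ids, positions$id), , drop = FALSE]
    test_feat <- pos_of(test_ids)
    bg_feat <- lapply(seq_len(n_sets), function(j) pos_of(sets[, j]))
    count <- function(feat, members) sum(cpgs_in_intervals(feat, members))
  }
  rows <- lapply(names(term_list), function(tm) {
    members <- term_list[[tm]]
    t_ov <- count(test_feat, members)
    b_ov <- vapply(bg_feat, count, numeric(1), members = members)
    bg_mean <- mean(b_ov)
    data.frame(term = tm, test_overlap = t_ov, bg_mean = bg_mean,
               fold_change = t_ov / bg_mean,
               p_empirical = mean(b_ov >= t_ov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_empirical < alpha
  out[order(out$p_empirical, -out$fold_change), , drop = FALSE]
}

empty_enrichment <- function() {
  data.frame(term = character(0), test_overlap = numeric(0),
              bg_mean = numeric(0), fold_change = numeric(0),
              p_empirical = numeric(0), significant = logical(0))
}

#' End-to-end enrichment of suggestive association signals
#'
#' Selects the inclusive CpG set at the suggestive threshold
#' (\code{p < 1e-3} by default), builds methylation-matched backgrounds,
#' and runs gene-set and/or TFBS permutation enrichment.
#'
#' @param assoc association/meta results data frame (\code{probe, p}).
#' @param universe matching universe from [cpg_summary()].
#' @param gene_sets optional named list of gene sets (GMT).
#' @param tfbs optional BED data frame of TF binding intervals.
#' @param eqtm CpG-gene mapping table (required with \code{gene_sets}).
#' @param spec a [match_spec()].
#' @param p_suggestive suggestive inclusion threshold (default 1e-3).
#' @return list with \code{test_cpgs}, \code{backgrounds}, and ranked
#'   \code{gene_sets} / \code{tfbs} enrichment tables (empty when no CpG
#'   passes the threshold or the annotation is absent).
#' @export
run_enrichment <- function(assoc, universe, gene_sets = NULL, tfbs = NULL,
                           eqtm = NULL, spec = match_spec(),
                           p_suggestive = 1e-3) {
  test_ids <- assoc$probe[!is.na(assoc$p) & assoc$p < p_suggestive]
  if (!length(test_ids))
    return(list(test_cpgs = character(0), backgrounds = NULL,
                gene_sets = empty_enrichment(), tfbs = empty_enrichment()))
  test <- universe[match(test_ids, universe$id), , drop = FALSE]
  bg <- match_background(test, universe, spec)
  res_gs <- if (!is.null(gene_sets))
    overlap_enrichment(test_ids, bg, gene_sets, mode = "geneset",
                       eqtm = eqtm)
  else empty_enrichment()
  res_tf <- if (!is.null(tfbs))
    overlap_enrichment(test_ids, bg, tfbs, mode = "tfbs",
                       positions = universe[, c("id", "chrom", "pos")])
  else empty_enrichment()
  list(test_cpgs = test_ids, backgrounds = bg, gene_sets = res_gs,
       tfbs = res_tf)
}
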