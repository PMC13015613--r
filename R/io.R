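# Readers/writers for the tab-delimited interchange formats used across the
# pipeline, plus GMT and BED annotation files.

#' Read / write per-stratum association summary statistics
#'
#' The interchange format between the EWAS and meta-analysis stages: a
#' tab-delimited table with header columns \code{probe, chrom, pos, beta,
#' se, z, p, n} (and optionally \code{stratum}).
#'
#' @param path file path.
#' @param x an association results data frame.
#' @return \code{read_assoc} returns a data frame; \code{write_assoc}
#'   invisibly returns \code{path}.
#' @export
read_assoc <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe", "z", "p", "n")
  if (!all(need %in% names(x)))
    stop("association table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  x
}

#' @rdname read_assoc
#' @export
write_assoc <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write variant-level summary statistics
#'
#' Tab-delimited GWAS/QTL summary statistics with header columns
#' \code{variant, chrom, pos, ea, oa, beta, se, p, n} (effect and other
#' allele; effect sizes on the effect-allele dosage scale).
#'
#' @param path file path.
#' @param x a summary-statistics data frame.
#' @return \code{read_sumstats} returns a data frame; \code{write_sumstats}
#'   invisibly returns \code{path}.
#' @export
read_sumstats <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant", "beta", "se", "p")
  if (!all(need %in% names(x)))
    stop("summary statistics must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  x
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Reading delegates to \code{fgsea::gmtPathways}.  Writing emits the
#' standard tab-delimited layout: term, description, then one member per
#' field.
#'
#' @param path file path.
#' @param sets named list of character vectors (term -> members).
#' @param descriptions optional character vector of term descriptions.
#' @return \code{read_gmt} returns a named list of member vectors;
#'   \code{write_gmt} invisibly returns \code{path}.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED files are 0-based half-open; conversion to/from the package's
#' 1-based inclusive interval data frames (\code{chrom, start, end, name})
#' is handled by \code{rtracklayer}.
#'
#' @param path file path.
#' @param x data frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open, as in the file) and optionally \code{name}.
#' @return \code{read_bed} returns a data frame with 0-based half-open
#'   \code{start}/\code{end} (identical round-trip with \code{write_bed});
#'   \code{write_bed} invisibly returns \code{path}.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
  if (!is.null(x$name)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
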