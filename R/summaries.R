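#' Per-chromosome CNVR summaries
#'
#' For each chromosome of the genome (in reporting order, including
#' chromosomes with no CNVRs) this tabulates CNVR counts by type, density,
#' base coverage and length statistics. Density is the CNVR count divided by
#' the chromosome length in Mb; `covered_bp` is the length of the base-pair
#' union of the CNVRs (equal to the summed lengths, since merged CNVRs within
#' one view are disjoint). On a chromosome without CNVRs the length median
#' and mean are reported as 0 with `no_cnvrs = TRUE`.
#'
#' @param cnvrs A CNVR `GRanges` from [buildCnvrs()].
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A `data.frame` with one row per chromosome and columns `chrom`,
#'   `length_bp`, `n_total`, `n_dup`, `n_del`, `n_both`, `density_per_mb`,
#'   `covered_bp`, `coverage_fraction`, `median_length_bp`, `mean_length_bp`,
#'   `no_cnvrs`.
#' @export
summarizeCnvrs <- function(cnvrs, genome) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  cn <- factor(as.character(GenomicRanges::seqnames(cnvrs)), levels = chroms)
  w <- GenomicRanges::width(cnvrs)
  tab <- function(type) as.integer(table(cn[cnvrs$cnvr_type == type]))
  n_dup <- tab("DUP"); n_del <- tab("DEL"); n_both <- tab("BOTH")
  n_total <- as.integer(table(cn))
  covered <- vapply(seq_along(chroms), function(i) {
    sub <- cnvrs[cn == chroms[i]]
    sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(sub, ignore.strand = TRUE))))
  }, 0)
  med <- vapply(seq_along(chroms), function(i)
    if (n_total[i]) stats::median(w[cn == chroms[i]]) else 0, 0)
  mea <- vapply(seq_along(chroms), function(i)
    if (n_total[i]) mean(w[cn == chroms[i]]) else 0, 0)
  data.frame(chrom = chroms, length_bp = lens,
             n_total = n_total, n_dup = n_dup, n_del = n_del, n_both = n_both,
             density_per_mb = n_total / (lens / 1e6),
             covered_bp = covered,
             coverage_fraction = covered / lens,
             median_length_bp = med, mean_length_bp = mea,
             no_cnvrs = n_total == 0L,
             stringsAsFactors = FALSE)
}

#' Aggregate chromosome summaries into genome-wide totals
#'
#' Sums the per-chromosome counts and bases and recomputes the genome density
#' as total CNVR count over total length in Mb. Works on any data.frame with
#' `length_bp` and `n_total` columns (e.g. the output of [summarizeCnvrs()]
#' or a count table read with [readChromCounts()]); `n_dup`/`n_del`/`n_both`
#' and coverage columns are aggregated when present.
#'
#' @param summary A per-chromosome summary `data.frame`.
#' @return A one-row `data.frame` with the genome totals and
#'   `density_per_mb`.
#' @export
aggregateChromSummaries <- function(summary) {
  stopifnot(all(c("length_bp", "n_total") %in% names(summary)))
  out <- data.frame(length_bp = sum(as.numeric(summary$length_bp)),
                    n_total = sum(summary$n_total))
  for (col in c("n_dup", "n_del", "n_both", "covered_bp"))
    if (col %in% names(summary)) out[[col]] <- sum(summary[[col]])
  out$density_per_mb <- out$n_total / (out$length_bp / 1e6)
  if ("covered_bp" %in% names(out))
    out$coverage_fraction <- out$covered_bp / out$length_bp
  out
}

#' Read a per-chromosome CNVR count table
#'
#' Reads a TSV with columns `chrom`, `length_mb` and one or more count
#' columns, into the shape used by [aggregateChromSummaries()],
#' [dupDelRatio()] and [lengthCountCorrelation()]. The packaged fixture
#' `system.file("extdata", "pig_cnvr_chrom_counts.tsv", package = "cnvst")`
#' holds a published autosomal CNVR distribution from a resequencing
#' comparison of a Chinese indigenous pig breed (AQ) with Asian wild boars
#' (SS): per-chromosome totals and DUP/DEL counts for the joint and the two
#' per-population views.
#'
#' @param path TSV path.
#' @param scope Prefix selecting the count columns (the packaged fixture has
#'   `all_*`, `aq_*` and `ss_*` columns).
#' @return A `data.frame` with columns `chrom`, `length_bp`, `n_total` and,
#'   when present in the file, `n_dup`, `n_del`, `n_both`.
#' @export
readChromCounts <- function(path, scope = "all") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_mb") %in% names(df)))
  out <- data.frame(chrom = as.character(df$chrom),
                    length_bp = df$length_mb * 1e6)
  pick <- function(suffix) df[[paste0(scope, "_", suffix)]]
  if (is.null(pick("total")))
    stop("no columns for scope '", scope, "' in ", path)
  out$n_total <- pick("total")
  for (s in c("dup", "del")) if (!is.null(pick(s))) out[[paste0("n_", s)]] <- pick(s)
  if (!is.null(out$n_dup) && !is.null(out$n_del))
    out$n_both <- out$n_total - out$n_dup - out$n_del
  out
}

#' Duplication / deletion CNVR ratio
#'
#' Ratio of DUP-only to DEL-only CNVR counts; mixed-type (`BOTH`) regions are
#' excluded. Undefined (NA, with a warning) when there are no DEL regions.
#'
#' @param x Either a CNVR `GRanges` or a summary `data.frame` with `n_dup`
#'   and `n_del` columns.
#' @return A single numeric ratio.
#' @export
dupDelRatio <- function(x) {
  if (inherits(x, "GRanges")) {
    n_dup <- sum(x$cnvr_type == "DUP")
    n_del <- sum(x$cnvr_type == "DEL")
  } else {
    stopifnot(all(c("n_dup", "n_del") %in% names(x)))
    n_dup <- sum(x$n_dup); n_del <- sum(x$n_del)
  }
  if (n_del == 0L) {
    warning("no DEL CNVRs; DUP/DEL ratio undefined")
    return(NA_real_)
  }
  n_dup / n_del
}

#' Correlation of chromosome length with CNVR count and length
#'
#' Pearson correlation, across chromosomes, between chromosome length and
#' (a) the CNVR count and (b) the summed CNVR length (`covered_bp`). The
#' second value is `NA` when the summary carries no coverage column. A
#' zero-variance vector makes the corresponding coefficient undefined (`NA`,
#' with a warning).
#'
#' @param summary A per-chromosome summary `data.frame` (at least 3 rows).
#' @return Named numeric vector `c(r_count = ..., r_length = ...)`.
#' @export
lengthCountCorrelation <- function(summary) {
  stopifnot(nrow(summary) >= 3L)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance; correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  r_count <- safe_cor(summary$length_bp, summary$n_total)
  r_length <- if ("covered_bp" %in% names(summary))
    safe_cor(summary$length_bp, summary$covered_bp) else NA_real_
  c(r_count = r_count, r_length = r_length)
}
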