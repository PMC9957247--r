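#' Read a chromosome-sizes table as a Seqinfo
#'
#' The genome definition is the coordinate authority for every interval in the
#' pipeline: chromosome names must match call and annotation files verbatim
#' (no "chr" aliasing unless requested), and the row order of the file is the
#' reporting order used by all per-chromosome summaries.
#'
#' @param path A two-column (fai-like) TSV: chromosome name, length in bp.
#'   Extra columns are ignored; lines starting with `#` are comments.
#' @param stripChrPrefix If `TRUE`, a leading `"chr"` is removed from
#'   chromosome names so that `chr1`-style annotation files can be combined
#'   with bare-name call files.
#' @return A [GenomeInfoDb::Seqinfo] with one entry per chromosome.
#' @examples
#' tf <- tempfile()
#' writeLines(c("1\t1000000", "2\t500000"), tf)
#' readGenome(tf)
#' @export
readGenome <- function(path, stripChrPrefix = FALSE) {
  df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                          colClasses = c("character", "numeric"),
                          col.names = c("name", "length_bp"),
                          fill = FALSE, stringsAsFactors = FALSE)[, 1:2]
  if (nrow(df) == 0L) stop("genome file is empty: ", path)
  if (stripChrPrefix) df$name <- sub("^chr", "", df$name)
  if (anyDuplicated(df$name))
    stop("duplicated chromosome names in genome file: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  if (any(!is.finite(df$length_bp)) || any(df$length_bp <= 0) ||
      any(df$length_bp != round(df$length_bp)))
    stop("chromosome lengths must be positive integers (bp)")
  GenomeInfoDb::Seqinfo(seqnames = df$name, seqlengths = as.integer(df$length_bp))
}

#' Write a Seqinfo back to a chromosome-sizes TSV
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  df <- data.frame(name = GenomeInfoDb::seqnames(genome),
                   length_bp = GenomeInfoDb::seqlengths(genome))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Autosome lengths (Mb) of the Sus scrofa reference, chromosomes 1-18.
# Used both as the default simulation genome (scaled) and by the packaged
# chromosome-level CNVR distribution fixture.
.PIG_AUTOSOME_MB <- c(
  `1` = 274.33, `2` = 151.94, `3` = 132.85, `4` = 130.91, `5` = 104.53,
  `6` = 170.84, `7` = 121.84, `8` = 138.97, `9` = 139.51, `10` = 69.36,
  `11` = 79.17, `12` = 61.60, `13` = 208.34, `14` = 141.76, `15` = 140.41,
  `16` = 79.94, `17` = 63.49, `18` = 55.98)

#' Pig autosomes as a Seqinfo, optionally scaled down
#'
#' Returns the 18 Sus scrofa autosome lengths. `scale` shrinks every
#' chromosome by the same factor so that simulations preserve the true
#' relative chromosome sizes (chromosome 1 longest, 18 shortest) at a
#' desk-scale total; the default simulation uses `scale = 0.02`
#' (about 45 Mb in total).
#'
#' @param scale Multiplicative factor applied to all lengths.
#' @return A [GenomeInfoDb::Seqinfo] with chromosomes `"1"`..`"18"`.
#' @export
pigAutosomes <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  GenomeInfoDb::Seqinfo(seqnames = names(.PIG_AUTOSOME_MB),
                        seqlengths = as.integer(round(.PIG_AUTOSOME_MB * 1e6 * scale)))
}

# Shared check: all seqnames of a GRanges are declared in the genome.
.checkChroms <- function(gr, genome, what = "interval") {
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                 GenomeInfoDb::seqnames(genome))
  if (length(bad))
    stop(what, "s on chromosomes absent from the genome definition: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
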