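.fmt6 <- function(x) {
  # stable TSV rendering for floats: 6 significant digits
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write / read a CNVR table
#'
#' TSV with a fixed column order (`cnvr_id`, `chrom`, `start`, `end`,
#' `length_bp`, `cnvr_type`, `n_calls`, `n_samples`, `sample_ids`);
#' coordinates stay 1-based inclusive. `readCnvrTable()` is its inverse, so
#' a written table reads back to an identical `GRanges`.
#'
#' @param cnvrs A CNVR `GRanges` from [buildCnvrs()].
#' @param path Output/input TSV path.
#' @return `writeCnvrTable()`: `path`, invisibly. `readCnvrTable()`: a CNVR
#'   `GRanges`.
#' @export
writeCnvrTable <- function(cnvrs, path) {
  df <- data.frame(
    cnvr_id = cnvrs$cnvr_id,
    chrom = as.character(GenomicRanges::seqnames(cnvrs)),
    start = GenomicRanges::start(cnvrs),
    end = GenomicRanges::end(cnvrs),
    length_bp = GenomicRanges::width(cnvrs),
    cnvr_type = cnvrs$cnvr_type,
    n_calls = cnvrs$n_calls,
    n_samples = cnvrs$n_samples,
    sample_ids = vapply(cnvrs$sample_ids, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param genome A [GenomeInfoDb::Seqinfo] for the returned `GRanges`.
#' @rdname writeCnvrTable
#' @export
readCnvrTable <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character",
                                         sample_ids = "character"),
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    cnvr_id = df$cnvr_id,
    cnvr_type = df$cnvr_type,
    n_calls = as.integer(df$n_calls),
    n_samples = as.integer(df$n_samples),
    sample_ids = IRanges::CharacterList(strsplit(df$sample_ids, ",",
                                                 fixed = TRUE)),
    seqinfo = genome)
  gr
}

#' Write a VST table
#'
#' @param records The (possibly [selectTop()]-flagged) `DataFrame` from
#'   [computeVst()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeVstTable <- function(records, path) {
  df <- as.data.frame(records)
  for (col in c("vst", "v_total", "v_pop1", "v_pop2"))
    df[[col]] <- .fmt6(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write selected CNVRs as BED
#'
#' Converts the internal 1-based inclusive intervals back to BED's 0-based
#' half-open convention (internal `[100, 200]` becomes `99 200`). Column 4 is
#' the CNVR id; column 5, when `scores` is given, holds the VST value scaled
#' to BED's 0-1000 integer range.
#'
#' @param cnvrs A CNVR `GRanges`.
#' @param path Output BED path.
#' @param scores Optional numeric in `[0, 1]` (e.g. VST) per CNVR.
#' @return `path`, invisibly.
#' @export
writeSelectedBed <- function(cnvrs, path, scores = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cnvrs)),
                   start = GenomicRanges::start(cnvrs) - 1L,
                   end = GenomicRanges::end(cnvrs),
                   name = cnvrs$cnvr_id,
                   stringsAsFactors = FALSE)
  if (!is.null(scores)) df$score <- as.integer(round(1000 * scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
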