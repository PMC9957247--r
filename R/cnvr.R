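#' Merge filtered CNV calls into CNV regions (CNVRs)
#'
#' CNVRs are the connected components of the call-overlap graph: two calls
#' are joined when they share at least one base pair on the 1-based inclusive
#' coordinates, and components are closed transitively (single linkage), so a
#' chain of pairwise-overlapping calls collapses into one region even when
#' its extremes do not touch. Each CNVR's interval is the envelope
#' (min start, max end) of its component, which for a connected component is
#' the contiguous union of its calls. Calls that merely abut
#' (`[100,200]` and `[201,300]`) share no base and stay separate.
#'
#' A CNVR is typed `DEL` when all member calls are deletions, `DUP` when all
#' are duplications, and `BOTH` for mixed membership.
#'
#' @param calls A `GRanges` of (filtered) calls with `sample_id`, `cnv_type`
#'   metadata.
#' @param genome A [GenomeInfoDb::Seqinfo]; defines the chromosome order of
#'   the output.
#' @return A `GRanges` sorted by (genome chromosome order, start) with
#'   metadata columns `cnvr_id` (`CNVR_<chrom>_<serial>`), `cnvr_type`,
#'   `n_calls`, `n_samples`, and `sample_ids` (a `CharacterList` of member
#'   samples).
#' @export
buildCnvrs <- function(calls, genome) {
  .checkChroms(calls, genome, "call")
  gr <- GenomicRanges::GRanges(seqnames = as.character(GenomicRanges::seqnames(calls)),
                               ranges = IRanges::ranges(calls), seqinfo = genome)
  # min.gapwidth = 0 merges only ranges sharing >= 1 bp; adjacency is kept apart
  cnvrs <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  cnvrs <- GenomicRanges::sort(cnvrs, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(cnvrs, gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (length(calls) && !identical(sort(unique(S4Vectors::subjectHits(ov))),
                                  seq_along(gr)))
    stop("internal error: a call was not assigned to any CNVR")
  f <- factor(S4Vectors::queryHits(ov), levels = seq_along(cnvrs))
  types <- split(calls$cnv_type[S4Vectors::subjectHits(ov)], f)
  samples <- split(calls$sample_id[S4Vectors::subjectHits(ov)], f)
  cnvr_type <- vapply(types, function(tt) {
    u <- unique(tt)
    if (length(u) == 1L) u else "BOTH"
  }, "")
  chrom <- as.character(GenomicRanges::seqnames(cnvrs))
  serial <- stats::ave(seq_along(cnvrs), chrom, FUN = seq_along)
  S4Vectors::mcols(cnvrs) <- S4Vectors::DataFrame(
    cnvr_id = sprintf("CNVR_%s_%d", chrom, serial),
    cnvr_type = unname(cnvr_type),
    n_calls = unname(as.integer(lengths(types))),
    n_samples = unname(vapply(samples, function(s) length(unique(s)), 0L)),
    sample_ids = unname(IRanges::CharacterList(lapply(samples, unique))))
  cnvrs
}

#' Map calls to the CNVR containing them
#'
#' @param cnvrs CNVRs from [buildCnvrs()].
#' @param calls The call set the CNVRs were built from.
#' @return An integer vector, parallel to `calls`, of indices into `cnvrs`.
#' @export
callMembership <- function(cnvrs, calls) {
  ov <- GenomicRanges::findOverlaps(calls, cnvrs, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (length(calls) &&
      (length(ov) != length(calls) || anyDuplicated(S4Vectors::queryHits(ov))))
    stop("calls do not map one-to-one onto CNVRs; were the CNVRs built from ",
         "this call set?")
  idx <- integer(length(calls))
  idx[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  idx
}

#' Per-population CNVR views
#'
#' Rebuilds CNVRs from each population's calls alone (a re-merge, not a
#' subset of the joint regions, since envelopes differ when one population's
#' calls are removed), alongside the joint all-samples merge. Mirrors the
#' convention under which the two populations of a study have different CNVR
#' counts and size ranges.
#'
#' @param calls A filtered call `GRanges` carrying a `population` metadata
#'   column (see [readCallSet()]).
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A named list of CNVR `GRanges`: element `"all"` plus one per
#'   population.
#' @export
populationViews <- function(calls, genome) {
  if (is.null(calls$population)) stop("calls lack a 'population' column")
  pops <- sort(unique(calls$population))
  if (any(!nzchar(pops))) stop("empty population label")
  views <- c(list(all = buildCnvrs(calls, genome)),
             lapply(stats::setNames(pops, pops), function(p)
               buildCnvrs(calls[calls$population == p], genome)))
  views
}
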