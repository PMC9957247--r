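#' CNVRExperiment: CNVR-by-sample copy numbers
#'
#' An S4 container for the copy-number matrix, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are CNVRs (with
#' their `GRanges` and merge metadata as `rowRanges`), columns are samples,
#' and the single assay `"cn"` holds estimated copy numbers (diploid = 2.0;
#' a cell is never missing — absence of a call means the diploid baseline).
#' `colData` carries the `population` label of every sample.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @aliases CNVRExperiment
#' @exportClass CNVRExperiment
setClass("CNVRExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("CNVRExperiment", function(object) {
  msg <- NULL
  if (!("cn" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'cn' is required")
  else {
    cn <- SummarizedExperiment::assay(object, "cn")
    if (anyNA(cn)) msg <- c(msg, "assay 'cn' must have no missing cells")
    else if (any(cn < 0)) msg <- c(msg, "copy numbers must be non-negative")
  }
  if (!("population" %in% names(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must carry a 'population' column")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn CNVRExperiment-accessors the copy-number matrix
#'   (CNVRs x samples).
#' @export
setGeneric("cnMatrix", function(x) standardGeneric("cnMatrix"))

#' @describeIn CNVRExperiment-accessors population label per sample.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Accessors for CNVRExperiment
#'
#' @param x A [CNVRExperiment-class] object.
#' @name CNVRExperiment-accessors
#' @aliases cnMatrix populations cnMatrix,CNVRExperiment-method
#'   populations,CNVRExperiment-method
NULL

#' @rdname CNVRExperiment-accessors
#' @export
setMethod("cnMatrix", "CNVRExperiment", function(x)
  SummarizedExperiment::assay(x, "cn"))

#' @rdname CNVRExperiment-accessors
#' @export
setMethod("populations", "CNVRExperiment", function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$population),
                  colnames(x)))

setMethod("show", "CNVRExperiment", function(object) {
  methods::callNextMethod()
  pops <- table(populations(object))
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
})

#' Estimate the copy-number matrix from calls and CNVRs
#'
#' For CNVR r and sample s, the estimated copy number is `2 *` the
#' base-weighted mean read depth over r: bases covered by one of s's calls
#' contribute the call's normalized RD (where a sample's own calls overlap,
#' the mean RD of the covering calls), and uncovered bases contribute the
#' diploid baseline RD of 1.0. A sample with no call overlapping the CNVR
#' therefore gets exactly 2.0; a duplication call with RD 1.5 spanning the
#' whole region gives 3.0.
#'
#' This estimator stands in for a dedicated read-depth genotyper: it uses
#' only what the call files report.
#'
#' @param cnvrs CNVRs from [buildCnvrs()] on the joint call set.
#' @param calls The same filtered call `GRanges` the CNVRs were built from.
#' @param manifest Sample manifest `data.frame` (`sample_id`, `population`);
#'   defines the column order, and samples without calls still get a column.
#' @param roundCN Round copy numbers to the nearest integer (off by default;
#'   continuous values retain more of the depth signal).
#' @return A [CNVRExperiment-class].
#' @export
buildCNMatrix <- function(cnvrs, calls, manifest, roundCN = FALSE) {
  genome <- GenomeInfoDb::seqinfo(cnvrs)
  .checkChroms(calls, genome, "call")
  if (!all(calls$sample_id %in% manifest$sample_id))
    stop("calls from samples missing in the manifest: ",
         paste(setdiff(unique(calls$sample_id), manifest$sample_id),
               collapse = ", "))
  chroms <- as.character(GenomicRanges::seqnames(cnvrs))
  cn <- matrix(2, nrow = length(cnvrs), ncol = nrow(manifest),
               dimnames = list(cnvrs$cnvr_id, manifest$sample_id))
  rng_by_chr <- split(IRanges::ranges(cnvrs), chroms)
  row_by_chr <- split(seq_along(cnvrs), chroms)
  for (j in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[j]
    cs <- calls[calls$sample_id == s]
    if (!length(cs)) next
    cov_rd <- GenomicRanges::coverage(cs, weight = cs$rd)
    cov_n <- GenomicRanges::coverage(cs)
    for (chr in unique(as.character(GenomicRanges::seqnames(cs)))) {
      rows <- row_by_chr[[chr]]
      if (is.null(rows) || !length(rows)) next
      num <- cov_rd[[chr]]
      den <- cov_n[[chr]]
      uncov <- den == 0L
      num[uncov] <- 1
      den[uncov] <- 1L
      eff <- num / den
      v <- IRanges::Views(eff, rng_by_chr[[chr]])
      cn[rows, j] <- 2 * IRanges::viewMeans(v)
    }
  }
  if (roundCN) cn <- round(cn)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cn = cn),
    rowRanges = cnvrs,
    colData = S4Vectors::DataFrame(population = manifest$population,
                                   row.names = manifest$sample_id))
  methods::new("CNVRExperiment", se)
}
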