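# Shared fixtures and independent oracles for the test suite.

testGenome <- function(lengths = c(`1` = 1e6, `2` = 5e5)) {
  GenomeInfoDb::Seqinfo(seqnames = names(lengths),
                        seqlengths = as.integer(lengths))
}

# Quick call constructor with defaults that pass the high-confidence filters.
mkCalls <- function(start, end, chrom = "1", sample = "s1", type = "DEL",
                    rd = NULL, e = 1e-4, genome = testGenome()) {
  n <- length(start)
  type <- rep_len(type, n)
  if (is.null(rd)) rd <- ifelse(type == "DEL", 0.4, 1.6)
  cnvCalls(chrom = rep_len(chrom, n), start = start, end = end,
           sampleID = rep_len(sample, n), cnvType = type,
           rd = rep_len(rd, n), eValue = rep_len(e, n), genome = genome)
}

# Brute-force merge oracle: mark occupied bases on a bitmap and read off
# maximal runs. Only feasible for small spans; used to validate buildCnvrs.
bruteMerge <- function(starts, ends, span) {
  occ <- logical(span)
  for (i in seq_along(starts)) occ[starts[i]:ends[i]] <- TRUE
  r <- rle(occ)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1L
  data.frame(start = start_at[r$values], end = stop_at[r$values])
}

# From-definition Pearson correlation (sum formula), as an independent check.
pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Mean silhouette of a 2-group labelling on a 1-d coordinate.
silhouette1d <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(abs(x[i] - x[own & seq_along(x) != i]))
    b <- mean(abs(x[i] - x[!own]))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

table1Path <- function() {
  system.file("extdata", "pig_cnvr_chrom_counts.tsv", package = "cnvst",
              mustWork = TRUE)
}

# Small, fast simulation settings for pipeline-level tests.
smallSimParams <- function(seed = 1L, ...) {
  simParams(seed = seed, genome = pigAutosomes(0.004),
            nSharedCnvrs = 180L, nDiffCnvrs = 6L,
            nBackgroundGenes = 60L, nBackgroundQtls = 10L, ...)
}

# Build a CNVRExperiment directly from a CN matrix (rows auto-named).
mkExperiment <- function(cn, populations) {
  if (is.null(rownames(cn)))
    rownames(cn) <- sprintf("CNVR_1_%d", seq_len(nrow(cn)))
  if (is.null(colnames(cn)))
    colnames(cn) <- sprintf("s%02d", seq_len(ncol(cn)))
  rr <- GenomicRanges::GRanges("1", IRanges::IRanges(
    start = seq_len(nrow(cn)) * 1000L, width = 500L),
    cnvr_id = rownames(cn))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cn = cn), rowRanges = rr,
    colData = S4Vectors::DataFrame(population = populations,
                                   row.names = colnames(cn)))
  methods::new("CNVRExperiment", se)
}
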