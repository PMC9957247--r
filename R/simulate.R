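#' Parameters for the two-population CNV call simulator
#'
#' The generator emulates the input side of a two-population read-depth CNV
#' study: per-sample CNVnator-dialect call files for an unbalanced design
#' (24 + 6 samples by default) on the pig autosomes scaled to desk size,
#' with planted CNV regions of known class, multiplicative read-depth noise,
#' call-boundary jitter, and sub-threshold junk calls that exercise the
#' high-confidence filters.
#'
#' Two region classes are planted on non-overlapping intervals:
#' * *shared* regions segregate in both populations at mid-range carrier
#'   frequencies (uniform within +/- 0.05 of `carrierFreqShared`; CNVRs
#'   ascertained across a 30-sample panel are biased toward common variants).
#'   The two population frequencies additionally drift apart by a bounded
#'   offset of magnitude `driftRange` with random sign — the genome-wide
#'   divergence that makes two real populations separable by PCA and
#'   clustering, while staying far below the planted selection signal.
#' * *differentiated* regions carry the selection signal: carrier frequencies
#'   `diffFreqs` (default 0.9 in population 1 vs 0.1 in population 2).
#'
#' Carrier counts are exact by design: a region at frequency `f` in a
#' population of `n` samples gets `round(f * n)` carriers, drawn uniformly at
#' random. Planting exact frequencies keeps the truth classes exact in the
#' generated sample — under binomial carrier sampling a region planted as
#' differentiated could realize as undifferentiated (and vice versa,
#' especially with only 6 samples in the second population), which would make
#' recovery scoring against the truth labels ill-posed. The corresponding
#' population-level sampling noise of real studies is deliberately not
#' emulated (see the vignette).
#'
#' Carriers of a region get the region's integer copy-number state (shared
#' regions default to single-copy changes, 1 or 3; differentiated regions to
#' homozygous deletion or double duplication, 0 or 4); non-carriers stay
#' diploid and emit no call. A carrier call's RD is `(CN/2) * exp(N(0,
#' rdNoiseSd))` and each endpoint is jittered by up to `boundaryJitterBp`.
#' False-positive calls arrive at `fpRatePerMb` per sample with RD drawn to
#' straddle the filter thresholds (U(0.6, 0.8) or U(1.25, 1.4)), lengths down
#' to 300 bp, and a `junkEValueFrac` share of e-values above 0.01.
#'
#' @param seed Integer seed; the same seed reproduces byte-identical output.
#' @param genome A [GenomeInfoDb::Seqinfo] (default: pig autosomes at 2% of
#'   their true lengths, preserving relative chromosome sizes).
#' @param popNames Labels of the two populations.
#' @param nPop1,nPop2 Sample counts per population.
#' @param nSharedCnvrs,nDiffCnvrs Number of planted regions per class. The
#'   defaults give roughly 2000 realized CNVRs of which the 20 differentiated
#'   ones are about 1%, mirroring the proportion selected at a top-1% scan.
#' @param carrierFreqShared Mean carrier frequency of shared regions
#'   (per-region frequencies are uniform within +/- 0.05 of it).
#' @param diffFreqs Carrier frequencies `c(pop1, pop2)` of differentiated
#'   regions.
#' @param cnStates List with integer copy-number pools `shared` and
#'   `differentiated` sampled per region.
#' @param driftRange Range `c(min, max)` of the absolute between-population
#'   frequency offset of shared regions (sign random per region).
#' @param rdNoiseSd Lognormal sigma of the multiplicative RD noise.
#' @param boundaryJitterBp Maximum per-endpoint jitter (must be below half
#'   the minimum region length).
#' @param fpRatePerMb Expected false-positive calls per Mb per sample.
#' @param junkEValueFrac Fraction of false-positive calls given an e-value
#'   above the 0.01 filter threshold.
#' @param regionLengthRange Planted region length range (bp).
#' @param minGapBp Minimum gap between planted regions (kept above twice the
#'   jitter so neighbouring regions cannot merge).
#' @param nBackgroundGenes,nBackgroundQtls,nTerms Size of the synthetic
#'   annotation files.
#' @return A `cnvSimParams` list.
#' @export
simParams <- function(seed = 1L,
                      genome = pigAutosomes(0.02),
                      popNames = c("AQ", "SS"),
                      nPop1 = 24L, nPop2 = 6L,
                      nSharedCnvrs = 2250L, nDiffCnvrs = 21L,
                      carrierFreqShared = 0.27,
                      diffFreqs = c(0.9, 0.1),
                      cnStates = list(shared = c(1L, 3L),
                                      differentiated = c(0L, 4L)),
                      driftRange = c(0.15, 0.45),
                      rdNoiseSd = 0.05,
                      boundaryJitterBp = 200L,
                      fpRatePerMb = 0.3,
                      junkEValueFrac = 0.5,
                      regionLengthRange = c(1500L, 8000L),
                      minGapBp = 1000L,
                      nBackgroundGenes = 400L,
                      nBackgroundQtls = 30L,
                      nTerms = 25L) {
  stopifnot(nPop1 >= 1L, nPop2 >= 1L, length(popNames) == 2L,
            all(diffFreqs >= 0 & diffFreqs <= 1),
            carrierFreqShared > 0, carrierFreqShared < 1,
            length(driftRange) == 2L, all(driftRange >= 0), driftRange[2] < 1,
            carrierFreqShared > 0.05, carrierFreqShared < 0.95,
            rdNoiseSd >= 0, boundaryJitterBp >= 0,
            junkEValueFrac >= 0, junkEValueFrac <= 1,
            regionLengthRange[1] > 2 * boundaryJitterBp,
            all(c(cnStates$shared, cnStates$differentiated) != 2L))
  structure(as.list(environment()), class = "cnvSimParams")
}

# Place region lengths on a chromosome without overlap, keeping minGapBp
# between neighbours; errors when they cannot fit.
.placeRegions <- function(lens, chromLen, minGap) {
  k <- length(lens)
  if (!k) return(integer())
  need <- sum(lens) + (k + 1) * minGap
  if (need > chromLen)
    stop("planted regions cannot fit without overlap (need ", need,
         " bp, chromosome has ", chromLen, ")")
  free <- chromLen - need
  w <- stats::runif(k + 1)
  extra <- floor(w / sum(w) * free)
  starts <- minGap + extra[1] + 1 +
    cumsum(c(0, lens[seq_len(k - 1)] + minGap + extra[seq_len(k - 1) + 1L]))
  as.integer(starts)
}

#' Simulate a two-population CNV call study with known ground truth
#'
#' Writes a ready-to-run input directory: `calls/<sample>.tsv` in the
#' CNVnator output dialect, `manifest.tsv`, `genome.tsv`, synthetic
#' `genes.bed` and `qtls.bed` (one gene planted inside every differentiated
#' region, plus background genes and QTLs), `gene2term.tsv` (differentiated-
#' region genes share one marker term so enrichment has signal), and
#' `truth_regions.tsv` / `truth_carriers.tsv` for scoring.
#'
#' @param params A [simParams()] object.
#' @param dir Output directory (created if absent).
#' @return A list with the file paths (`manifest`, `genome`, `genes`, `qtls`,
#'   `gene2term`, `truthRegions`, `truthCarriers`, `callDir`), the truth as a
#'   `GRanges` (`truth`), the carrier table (`carriers`), and `params`.
#' @export
simulateCnvData <- function(params = simParams(), dir = tempfile("cnvsim")) {
  stopifnot(inherits(params, "cnvSimParams"))
  p <- params
  set.seed(p$seed)
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  genome <- p$genome
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- stats::setNames(as.numeric(GenomeInfoDb::seqlengths(genome)), chroms)

  ## ---- plant regions -------------------------------------------------
  n <- p$nSharedCnvrs + p$nDiffCnvrs
  rlen <- as.integer(round(stats::runif(n, p$regionLengthRange[1],
                                        p$regionLengthRange[2])))
  rchrom <- sample(chroms, n, replace = TRUE, prob = lens)
  start <- integer(n)
  for (chr in chroms) {
    i <- which(rchrom == chr)
    if (length(i)) start[i] <- .placeRegions(rlen[i], lens[[chr]], p$minGapBp)
  }
  end <- start + rlen - 1L
  class <- rep("shared", n)
  class[sample.int(n, p$nDiffCnvrs)] <- "differentiated"
  is_diff <- class == "differentiated"

  state <- integer(n)
  state[!is_diff] <- sample(p$cnStates$shared, sum(!is_diff), replace = TRUE)
  state[is_diff] <- sample(p$cnStates$differentiated, sum(is_diff),
                           replace = TRUE)

  ## ---- per-population carrier frequencies ----------------------------
  m <- p$carrierFreqShared
  f_anc <- stats::runif(n, m - 0.05, m + 0.05)
  delta <- sample(c(-1, 1), n, replace = TRUE) *
    stats::runif(n, p$driftRange[1], p$driftRange[2])
  # frequency floor keeps at least one pop-1 carrier per shared region, so a
  # region can never look private to the smaller population
  f1 <- pmin(pmax(f_anc + delta / 2, 0.04), 0.96)
  f2 <- pmin(pmax(f_anc - delta / 2, 0.04), 0.96)
  f1[is_diff] <- p$diffFreqs[1]
  f2[is_diff] <- p$diffFreqs[2]

  ## ---- carriers and calls --------------------------------------------
  # exact design: round(f * n) carriers per population, drawn uniformly
  samples <- c(sprintf("%s_%02d", p$popNames[1], seq_len(p$nPop1)),
               sprintf("%s_%02d", p$popNames[2], seq_len(p$nPop2)))
  pops <- rep(p$popNames, c(p$nPop1, p$nPop2))
  ns <- length(samples)
  k1 <- as.integer(round(f1 * p$nPop1))
  k2 <- as.integer(round(f2 * p$nPop2))
  carrier <- matrix(FALSE, n, ns,
                    dimnames = list(sprintf("region_%04d", seq_len(n)),
                                    samples))
  for (i in seq_len(n)) {
    if (k1[i]) carrier[i, sample.int(p$nPop1, k1[i])] <- TRUE
    if (k2[i]) carrier[i, p$nPop1 + sample.int(p$nPop2, k2[i])] <- TRUE
  }

  idx <- which(carrier, arr.ind = TRUE)
  reg <- idx[, 1L]; smp <- idx[, 2L]
  J <- p$boundaryJitterBp
  jit <- function(k) as.integer(round(stats::runif(k, -J, J)))
  cstart <- pmax(1L, start[reg] + jit(length(reg)))
  cend <- pmin(as.integer(lens[rchrom[reg]]), end[reg] + jit(length(reg)))
  rd <- (state[reg] / 2) * exp(stats::rnorm(length(reg), 0, p$rdNoiseSd))
  calls <- data.frame(
    sample = samples[smp],
    chrom = rchrom[reg],
    start = cstart, end = cend,
    type = ifelse(state[reg] < 2L, "deletion", "duplication"),
    rd = rd,
    e = stats::runif(length(reg), 0, 0.005),
    stringsAsFactors = FALSE)

  ## ---- false positives / junk ----------------------------------------
  totMb <- sum(lens) / 1e6
  nfp <- stats::rpois(ns, p$fpRatePerMb * totMb)
  if (sum(nfp)) {
    k <- sum(nfp)
    fchrom <- sample(chroms, k, replace = TRUE, prob = lens)
    flen <- as.integer(round(stats::runif(k, 300, 3000)))
    fstart <- as.integer(floor(stats::runif(k, 1, lens[fchrom] - flen)))
    isdel <- stats::runif(k) < 0.5
    frd <- ifelse(isdel, stats::runif(k, 0.6, 0.8), stats::runif(k, 1.25, 1.4))
    junk <- stats::runif(k) < p$junkEValueFrac
    fe <- ifelse(junk, stats::runif(k, 0.02, 0.5), stats::runif(k, 0, 0.005))
    calls <- rbind(calls, data.frame(
      sample = rep(samples, nfp),
      chrom = fchrom, start = fstart, end = fstart + flen - 1L,
      type = ifelse(isdel, "deletion", "duplication"),
      rd = frd, e = fe, stringsAsFactors = FALSE))
  }

  ## ---- write call files + manifest ------------------------------------
  chr_rank <- match(calls$chrom, chroms)
  for (s in samples) {
    cs <- calls[calls$sample == s, , drop = FALSE]
    cs <- cs[order(chr_rank[calls$sample == s], cs$start, cs$end), ,
             drop = FALSE]
    lines <- sprintf("%s\t%s:%d-%d\t%d\t%s\t%s\t%s\t%s\t%s\t0",
                     cs$type, cs$chrom, cs$start, cs$end,
                     cs$end - cs$start + 1L,
                     .fmt6(cs$rd), .fmt6(cs$e), .fmt6(cs$e), .fmt6(cs$e),
                     .fmt6(cs$e))
    writeLines(lines, file.path(dir, "calls", paste0(s, ".tsv")))
  }
  manifest <- data.frame(sample_id = samples, population = pops,
                         call_file = file.path("calls", paste0(samples, ".tsv")),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGenome(genome, file.path(dir, "genome.tsv"))

  ## ---- synthetic annotation -------------------------------------------
  di <- which(is_diff)
  glen <- pmin(2000L, rlen[di] %/% 2L)
  genes <- data.frame(chrom = rchrom[di],
                      start = start[di] + (rlen[di] - glen) %/% 2L,
                      end = integer(length(di)),
                      id = sprintf("geneD%03d", seq_along(di)),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + glen - 1L
  nbg <- p$nBackgroundGenes
  bchrom <- sample(chroms, nbg, replace = TRUE, prob = lens)
  blen <- as.integer(round(stats::runif(nbg, 1000, 5000)))
  bstart <- as.integer(floor(stats::runif(nbg, 1, lens[bchrom] - blen)))
  genes <- rbind(genes, data.frame(chrom = bchrom, start = bstart,
                                   end = bstart + blen - 1L,
                                   id = sprintf("geneB%03d", seq_len(nbg)),
                                   stringsAsFactors = FALSE))
  genes <- genes[order(match(genes$chrom, chroms), genes$start), ]
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$id),
    file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  qdi <- di[seq_len(ceiling(length(di) / 2))]
  qtl <- data.frame(chrom = rchrom[qdi],
                    start = pmax(1L, start[qdi] - 5000L),
                    end = pmin(as.integer(lens[rchrom[qdi]]), end[qdi] + 5000L),
                    stringsAsFactors = FALSE)
  qchrom <- sample(chroms, p$nBackgroundQtls, replace = TRUE, prob = lens)
  qlen <- as.integer(round(stats::runif(p$nBackgroundQtls, 20000, 50000)))
  qstart <- as.integer(floor(stats::runif(p$nBackgroundQtls, 1,
                                          lens[qchrom] - qlen)))
  qtl <- rbind(qtl, data.frame(chrom = qchrom, start = qstart,
                               end = qstart + qlen - 1L))
  qtl <- qtl[order(match(qtl$chrom, chroms), qtl$start), ]
  qtl$id <- sprintf("QTL%03d", seq_len(nrow(qtl)))
  utils::write.table(
    data.frame(qtl$chrom, qtl$start - 1L, qtl$end, qtl$id),
    file.path(dir, "qtls.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  terms <- sprintf("T%03d", seq_len(p$nTerms))
  ng <- nrow(genes)
  nt <- sample(1:3, ng, replace = TRUE)
  g2t <- data.frame(
    gene_id = rep(genes$id, nt),
    term_id = unlist(lapply(nt, function(k) sample(terms, k))),
    stringsAsFactors = FALSE)
  g2t <- rbind(g2t, data.frame(gene_id = sprintf("geneD%03d", seq_along(di)),
                               term_id = "T_DIFF"))
  g2t$term_name <- ifelse(g2t$term_id == "T_DIFF",
                          "planted differentiation marker term",
                          paste("synthetic term", g2t$term_id))
  g2t <- unique(g2t[order(g2t$gene_id, g2t$term_id), ])
  utils::write.table(g2t, file.path(dir, "gene2term.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- truth ----------------------------------------------------------
  truth_df <- data.frame(
    region_id = rownames(carrier), chrom = rchrom,
    start = start, end = end, class = class, cn_state = state,
    freq_pop1 = round(f1, 6), freq_pop2 = round(f2, 6),
    n_carriers_pop1 = rowSums(carrier[, pops == p$popNames[1], drop = FALSE]),
    n_carriers_pop2 = rowSums(carrier[, pops == p$popNames[2], drop = FALSE]),
    stringsAsFactors = FALSE)
  truth_df <- truth_df[order(match(truth_df$chrom, chroms), truth_df$start), ]
  utils::write.table(truth_df, file.path(dir, "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  carr <- which(carrier, arr.ind = TRUE)
  carr_df <- data.frame(region_id = rownames(carrier)[carr[, 1]],
                        sample_id = samples[carr[, 2]],
                        stringsAsFactors = FALSE)
  carr_df <- carr_df[order(carr_df$region_id, carr_df$sample_id), ]
  utils::write.table(carr_df, file.path(dir, "truth_carriers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- GenomicRanges::GRanges(
    seqnames = truth_df$chrom,
    ranges = IRanges::IRanges(truth_df$start, truth_df$end),
    region_id = truth_df$region_id, class = truth_df$class,
    cn_state = truth_df$cn_state,
    freq_pop1 = truth_df$freq_pop1, freq_pop2 = truth_df$freq_pop2,
    seqinfo = genome)

  list(dir = dir,
       manifest = file.path(dir, "manifest.tsv"),
       genome = file.path(dir, "genome.tsv"),
       genes = file.path(dir, "genes.bed"),
       qtls = file.path(dir, "qtls.bed"),
       gene2term = file.path(dir, "gene2term.tsv"),
       truthRegions = file.path(dir, "truth_regions.tsv"),
       truthCarriers = file.path(dir, "truth_carriers.tsv"),
       callDir = file.path(dir, "calls"),
       truth = truth, carriers = carr_df, params = p)
}

#' Read a simulated truth-region table
#'
#' @param path `truth_regions.tsv` written by [simulateCnvData()].
#' @param genome The matching [GenomeInfoDb::Seqinfo].
#' @return A `GRanges` with `region_id`, `class`, `cn_state` and frequency
#'   columns.
#' @export
readTruthRegions <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"),
                          stringsAsFactors = FALSE)
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(df$start, df$end),
                         region_id = df$region_id, class = df$class,
                         cn_state = df$cn_state,
                         freq_pop1 = df$freq_pop1, freq_pop2 = df$freq_pop2,
                         seqinfo = genome)
}

#' Score recovery of planted differentiated regions
#'
#' @param truth Truth `GRanges` from [simulateCnvData()] or
#'   [readTruthRegions()].
#' @param cnvrs The CNVR `GRanges` the selection refers to.
#' @param selected Logical vector over `cnvrs` (e.g. the `top1` column of a
#'   [selectTop()] result).
#' @return A list: `sensitivity` (fraction of differentiated truth regions
#'   overlapped by a selected CNVR) and `fdr` (fraction of selected CNVRs
#'   overlapping no differentiated truth region; `NA` when nothing is
#'   selected).
#' @export
scoreRecovery <- function(truth, cnvrs, selected) {
  stopifnot(length(selected) == length(cnvrs))
  diff <- truth[truth$class == "differentiated"]
  sel <- cnvrs[selected]
  sensitivity <- if (length(diff))
    mean(IRanges::overlapsAny(diff, sel, minoverlap = 1L)) else NA_real_
  fdr <- if (length(sel))
    mean(!IRanges::overlapsAny(sel, diff, minoverlap = 1L)) else NA_real_
  list(sensitivity = sensitivity, fdr = fdr)
}
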