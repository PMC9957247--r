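#' Overlap CNVRs with annotation intervals
#'
#' Reports every (CNVR, feature) pair sharing at least `minOverlapBp` bases
#' on the inclusive coordinates, with the overlap width and the Jaccard index
#' (intersection / union of the two intervals). Features on chromosomes
#' unknown to the CNVRs' genome are skipped with a warning.
#'
#' @param cnvrs A CNVR `GRanges` (typically the selected top-VST regions).
#' @param features An annotation `GRanges` from [readAnnotationBed()] or
#'   [readAnnotationGff3()].
#' @param minOverlapBp Minimum shared bases (default 1).
#' @param minJaccard Optional minimum Jaccard index filter (default 0, off).
#' @return A `data.frame` with columns `cnvr_id`, `feature_id`,
#'   `feature_class`, `overlap_bp`, `jaccard`.
#' @export
overlapAnnotations <- function(cnvrs, features, minOverlapBp = 1L,
                               minJaccard = 0) {
  genome <- GenomeInfoDb::seqinfo(cnvrs)
  known <- as.character(GenomicRanges::seqnames(features)) %in%
    GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    warning(sum(!known), " feature(s) on chromosomes absent from the ",
            "genome; skipped")
    features <- features[known]
  }
  GenomeInfoDb::seqlevels(features, pruning.mode = "coarse") <-
    GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(features) <- genome
  ov <- GenomicRanges::findOverlaps(cnvrs, features,
                                    minoverlap = as.integer(minOverlapBp),
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(cnvrs)[q], IRanges::ranges(features)[s]))
  uni <- GenomicRanges::width(cnvrs)[q] + GenomicRanges::width(features)[s] - inter
  out <- data.frame(cnvr_id = cnvrs$cnvr_id[q],
                    feature_id = features$feature_id[s],
                    feature_class = features$feature_class[s],
                    overlap_bp = inter,
                    jaccard = inter / uni,
                    stringsAsFactors = FALSE)
  out[out$jaccard >= minJaccard, , drop = FALSE]
}

#' Hypergeometric term over-representation test
#'
#' Standard over-representation analysis of a selected gene set against a
#' gene-to-term map: for each term with at least one selected gene, the
#' upper-tail hypergeometric probability `P(X >= k)` of drawing `k` term
#' genes in `n` selected from a universe of `N` genes of which `K` carry the
#' term, with Benjamini-Hochberg adjustment across the tested terms.
#'
#' @param selectedGenes Character vector of selected gene ids (must lie in
#'   `universe`).
#' @param gene2term A `data.frame` with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param universe Character vector of all eligible gene ids (default: every
#'   gene in `gene2term`).
#' @return A `data.frame`, ordered by p-value, with `term_id`, `term_name`,
#'   `k_selected`, `K_term`, `n_selected`, `N_universe`, `p_value`,
#'   `q_value`.
#' @export
enrichTerms <- function(selectedGenes, gene2term,
                        universe = unique(gene2term$gene_id)) {
  stopifnot(all(c("gene_id", "term_id") %in% names(gene2term)))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  selectedGenes <- unique(as.character(selectedGenes))
  if (!all(selectedGenes %in% universe))
    stop("selected genes outside the universe: ",
         paste(utils::head(setdiff(selectedGenes, universe), 5L), collapse = ", "))
  g2t <- unique(gene2term[gene2term$gene_id %in% universe,
                          intersect(names(gene2term),
                                    c("gene_id", "term_id", "term_name"))])
  N <- length(universe); n <- length(selectedGenes)
  if (n == 0L || nrow(g2t) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      k_selected = integer(), K_term = integer(),
                      n_selected = integer(), N_universe = integer(),
                      p_value = numeric(), q_value = numeric()))
  by_term <- split(g2t$gene_id, g2t$term_id)
  k <- vapply(by_term, function(g) sum(selectedGenes %in% g), 0L)
  K <- lengths(by_term)
  keep <- k > 0L
  by_term <- by_term[keep]; k <- k[keep]; K <- K[keep]
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  nm <- if ("term_name" %in% names(g2t))
    g2t$term_name[match(names(by_term), g2t$term_id)] else names(by_term)
  out <- data.frame(term_id = names(by_term), term_name = nm,
                    k_selected = as.integer(k), K_term = as.integer(K),
                    n_selected = n, N_universe = N,
                    p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
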