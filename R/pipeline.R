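#' Run the full CNVR differentiation pipeline
#'
#' Orchestrates every stage on a config: read calls -> filter -> merge into
#' CNVRs -> per-population views -> chromosome/genome summaries -> copy-number
#' matrix -> VST -> top-percentile selection -> PCA and UPGMA tree ->
#' gene/QTL overlap -> term enrichment. Every intermediate is written as a
#' plain TSV/BED/Newick file under `outdir` with fixed names, so stages can
#' be re-examined or re-run independently, and a `run_manifest.yaml` records
#' the package version, the echoed config, input checksums and per-stage
#' record counts. Reruns on identical inputs produce identical files.
#'
#' @param config A YAML file path or an equivalent nested list. Recognised
#'   keys (all optional except `paths`): `paths` (`manifest`, `genome`,
#'   `genes`, `qtls`, `gene2term`), `io` (`e_value_column`,
#'   `strip_chr_prefix`), `filter` (`max_e_value`, `del_rd_max`,
#'   `dup_rd_min`, `min_length_bp`), `matrix` (`round_cn`), `vst`
#'   (`variance_denominator`, `fractions`), `annotate` (`min_overlap_bp`,
#'   `min_jaccard`).
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a list with the main in-memory results (`calls`,
#'   `views`, `experiment`, `vst`, `pca`, `tree`, `overlaps`, `enrichment`).
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$paths$manifest),
            !is.null(config$paths$genome))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- function(..., default = NULL) {
    v <- config
    for (k in c(...)) { v <- v[[k]]; if (is.null(v)) return(default) }
    v
  }
  stage <- function(name, ...) message("[", name, "] ", ...)

  genome <- readGenome(config$paths$genome,
                       stripChrPrefix = isTRUE(cfg("io", "strip_chr_prefix")))
  manifest <- readSampleManifest(config$paths$manifest)
  stage("read", nrow(manifest), " samples, ",
        length(GenomeInfoDb::seqnames(genome)), " chromosomes")
  npop <- length(unique(manifest$population))
  if (npop != 2L)
    stop("the VST stage requires exactly two populations; manifest has ",
         npop)
  calls <- readCallSet(manifest, genome,
                       eValueColumn = cfg("io", "e_value_column", default = 1L),
                       stripChrPrefix = isTRUE(cfg("io", "strip_chr_prefix")))
  stage("read", length(calls), " raw calls")

  fp <- cnvFilterParams(
    maxEValue = cfg("filter", "max_e_value", default = 0.01),
    delRdMax = cfg("filter", "del_rd_max", default = 0.7),
    dupRdMin = cfg("filter", "dup_rd_min", default = 1.3),
    minLengthBp = cfg("filter", "min_length_bp", default = 1000L))
  flt <- filterCalls(calls, fp)
  utils::write.table(flt$report, file.path(outdir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("filter", flt$report$n_kept, " of ", flt$report$n_total,
        " calls kept")

  views <- populationViews(flt$kept, genome)
  for (nm in names(views)) {
    writeCnvrTable(views[[nm]], file.path(outdir, paste0("cnvrs_", nm, ".tsv")))
    smry <- summarizeCnvrs(views[[nm]], genome)
    utils::write.table(smry, file.path(outdir, paste0("chrom_summary_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage("merge", nm, ": ", length(views[[nm]]), " CNVRs")
  }
  gsum <- do.call(rbind, lapply(names(views), function(nm) {
    g <- aggregateChromSummaries(summarizeCnvrs(views[[nm]], genome))
    cbind(scope = nm, g)
  }))
  utils::write.table(gsum, file.path(outdir, "genome_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cne <- buildCNMatrix(views$all, flt$kept, manifest,
                       roundCN = isTRUE(cfg("matrix", "round_cn")))
  cnm <- cnMatrix(cne)
  utils::write.table(
    data.frame(cnvr_id = rownames(cnm), round(cnm, 6), check.names = FALSE),
    file.path(outdir, "cn_matrix.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stage("matrix", nrow(cnm), " CNVRs x ", ncol(cnm), " samples")

  vst <- computeVst(cne, denominator = cfg("vst", "variance_denominator",
                                           default = "N"))
  fractions <- unlist(cfg("vst", "fractions", default = c(0.10, 0.01)))
  vst <- selectTop(vst, fractions = fractions)
  writeVstTable(vst, file.path(outdir, "vst.tsv"))
  thr <- S4Vectors::metadata(vst)$vst_thresholds
  for (nm in names(thr)) {
    sel <- vst[[nm]]
    writeSelectedBed(views$all[sel],
                     file.path(outdir, paste0("selected_", nm, ".bed")),
                     scores = vst$vst[sel])
    stage("select", nm, ": ", sum(sel), " CNVRs at threshold ",
          .fmt6(thr[[nm]]))
  }

  pca <- cnvPca(cne)
  utils::write.table(
    data.frame(sample_id = rownames(pca$coordinates),
               population = populations(cne)[rownames(pca$coordinates)],
               round(pca$coordinates, 6), check.names = FALSE),
    file.path(outdir, "pca_coordinates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(component = names(pca$varianceExplained),
               variance_explained = round(pca$varianceExplained, 6)),
    file.path(outdir, "pca_variance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tree <- upgmaTree(cne)
  ape::write.tree(tree, file.path(outdir, "tree.nwk"))
  stage("pca/tree", "PC1 explains ",
        round(100 * pca$varianceExplained[1], 2), "%")

  topcol <- names(thr)[length(thr)]          # smallest fraction
  selected <- views$all[vst[[topcol]]]
  overlaps <- list()
  for (what in c("genes", "qtls")) {
    if (is.null(config$paths[[what]])) next
    cls <- if (what == "genes") "gene" else "qtl"
    feats <- readAnnotationBed(config$paths[[what]], featureClass = cls)
    hits <- overlapAnnotations(
      selected, feats,
      minOverlapBp = cfg("annotate", "min_overlap_bp", default = 1L),
      minJaccard = cfg("annotate", "min_jaccard", default = 0))
    utils::write.table(hits, file.path(outdir, paste0(cls, "_overlaps.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    overlaps[[cls]] <- hits
    stage("annotate", nrow(hits), " ", cls, " overlap(s) for ",
          length(selected), " selected CNVRs")
  }

  enrichment <- NULL
  if (!is.null(config$paths$gene2term) && !is.null(overlaps$gene)) {
    g2t <- utils::read.table(config$paths$gene2term, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    enrichment <- enrichTerms(unique(overlaps$gene$feature_id), g2t)
    utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage("enrich", nrow(enrichment), " terms tested")
  }

  inputs <- unlist(config$paths)
  run <- list(package = "cnvst",
              version = as.character(utils::packageVersion("cnvst")),
              config = config,
              input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              counts = list(samples = nrow(manifest),
                            raw_calls = length(calls),
                            kept_calls = flt$report$n_kept,
                            cnvrs = stats::setNames(lapply(views, length),
                                                    names(views)),
                            selected = as.list(colSums(
                              as.data.frame(vst[, names(thr), drop = FALSE])))))
  yaml::write_yaml(run, file.path(outdir, "run_manifest.yaml"))

  invisible(list(genome = genome, manifest = manifest, calls = flt$kept,
                 filterReport = flt$report, views = views, experiment = cne,
                 vst = vst, pca = pca, tree = tree, overlaps = overlaps,
                 enrichment = enrichment))
}
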