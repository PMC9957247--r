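#' Construct a CNV call GRanges
#'
#' Calls are represented as a [GenomicRanges::GRanges] with 1-based, fully
#' inclusive coordinates (the CNVnator convention) and metadata columns
#' `sample_id`, `cnv_type` (`"DEL"` or `"DUP"`), `rd` (normalized read depth,
#' diploid is about 1.0) and `e_value`.
#'
#' @param chrom,start,end Interval coordinates (1-based inclusive).
#' @param sampleID Sample identifier, recycled to the number of calls.
#' @param cnvType `"DEL"` or `"DUP"` per call.
#' @param rd Normalized read depth per call.
#' @param eValue Significance value per call, in `[0, 1]`.
#' @param genome A [GenomeInfoDb::Seqinfo]; all `chrom` values must be
#'   declared in it.
#' @return A `GRanges` of CNV calls.
#' @export
cnvCalls <- function(chrom, start, end, sampleID, cnvType, rd, eValue, genome) {
  n <- length(start)
  stopifnot(length(end) == n, length(chrom) %in% c(1L, n))
  cnvType <- as.character(cnvType)
  if (!all(cnvType %in% c("DEL", "DUP")))
    stop("cnv_type must be 'DEL' or 'DUP'")
  if (any(end < start)) stop("call end < start")
  if (any(rd < 0)) stop("negative read depth")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start, end = end),
    sample_id = rep_len(as.character(sampleID), n),
    cnv_type = cnvType,
    rd = as.numeric(rd),
    e_value = as.numeric(eValue),
    seqinfo = genome)
  gr
}

#' Read one CNVnator output file
#'
#' Parses the whitespace-delimited CNVnator call dialect: a type keyword
#' containing `deletion` or `duplication`, a `chrom:start-end` coordinate
#' token, the call size, the normalized read depth, then one or more e-value
#' columns (CNVnator prints four, `e-val1` first). Coordinates are kept
#' 1-based inclusive. CNVnator prints several e-values per call; by default
#' the first (its primary t-test value) is used, which is the one the
#' downstream significance filter consumes — `eValueColumn` selects another.
#'
#' Rows are never dropped silently: any malformed row aborts with its line
#' number.
#'
#' @param path Path to the call file. An empty file yields an empty result.
#' @param sampleID Sample identifier attached to every call.
#' @param genome A [GenomeInfoDb::Seqinfo]; calls on undeclared chromosomes
#'   are an error.
#' @param eValueColumn 1-based index among the e-value columns (columns 5+)
#'   of the value to keep.
#' @param stripChrPrefix Remove a leading `"chr"` from the coordinate token's
#'   chromosome name.
#' @return A `GRanges` of calls as in [cnvCalls()].
#' @export
readCnvnatorCalls <- function(path, sampleID, genome, eValueColumn = 1L,
                              stripChrPrefix = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(cnvCalls(character(), integer(), integer(), character(),
                    character(), numeric(), numeric(), genome))
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 5L))
    stop("line ", which(ncols < 5L)[1L], " of ", path,
         ": expected at least 5 columns, found ", min(ncols))
  type_kw <- vapply(fields, `[[`, "", 1L)
  cnv_type <- ifelse(grepl("deletion", type_kw),  "DEL",
              ifelse(grepl("duplication", type_kw), "DUP", NA_character_))
  if (anyNA(cnv_type))
    stop("line ", which(is.na(cnv_type))[1L], " of ", path,
         ": unknown CNV type keyword '", type_kw[is.na(cnv_type)][1L], "'")
  coord <- vapply(fields, `[[`, "", 2L)
  m <- regmatches(coord, regexec("^(.+):([0-9]+)-([0-9]+)$", coord))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("line ", which(bad)[1L], " of ", path,
         ": malformed coordinate token '", coord[bad][1L], "'")
  chrom <- vapply(m, `[[`, "", 2L)
  if (stripChrPrefix) chrom <- sub("^chr", "", chrom)
  start <- as.numeric(vapply(m, `[[`, "", 3L))
  end   <- as.numeric(vapply(m, `[[`, "", 4L))
  if (any(end < start))
    stop("line ", which(end < start)[1L], " of ", path, ": end < start")
  bad <- !(chrom %in% GenomeInfoDb::seqnames(genome))
  if (any(bad))
    stop("line ", which(bad)[1L], " of ", path,
         ": chromosome '", chrom[bad][1L],
         "' absent from the genome definition")
  rd <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ecol <- 4L + as.integer(eValueColumn)
  if (any(ncols < ecol))
    stop("e-value column ", eValueColumn, " requested but line ",
         which(ncols < ecol)[1L], " of ", path, " has only ",
         min(ncols) - 4L, " e-value column(s)")
  ev <- suppressWarnings(as.numeric(vapply(seq_along(fields),
                                           function(i) fields[[i]][[ecol]], "")))
  if (anyNA(rd) || anyNA(ev))
    stop("line ", which(is.na(rd) | is.na(ev))[1L], " of ", path,
         ": non-numeric read depth or e-value")
  cnvCalls(chrom, start, end, sampleID, cnv_type, rd, ev, genome)
}

#' Read a sample manifest
#'
#' @param path TSV with a header and columns `sample_id`, `population`,
#'   `call_file`. Relative `call_file` paths are resolved against `baseDir`
#'   (default: the manifest's directory).
#' @param baseDir Directory against which relative call-file paths resolve.
#' @return A `data.frame` with columns `sample_id`, `population`, `call_file`.
#' @export
readSampleManifest <- function(path, baseDir = dirname(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "call_file")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$call_file)
  df$call_file[rel] <- file.path(baseDir, df$call_file[rel])
  df
}

#' Read every sample's calls listed in a manifest
#'
#' @param manifest A data.frame as returned by [readSampleManifest()].
#' @inheritParams readCnvnatorCalls
#' @return A single `GRanges` of calls from all samples, with a `population`
#'   metadata column added from the manifest.
#' @export
readCallSet <- function(manifest, genome, eValueColumn = 1L,
                        stripChrPrefix = FALSE) {
  per <- lapply(seq_len(nrow(manifest)), function(i)
    readCnvnatorCalls(manifest$call_file[i], manifest$sample_id[i], genome,
                      eValueColumn = eValueColumn,
                      stripChrPrefix = stripChrPrefix))
  calls <- do.call(c, per)
  pop <- manifest$population[match(calls$sample_id, manifest$sample_id)]
  calls$population <- pop
  calls
}
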