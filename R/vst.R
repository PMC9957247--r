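#' VST population-differentiation statistic per CNVR
#'
#' For each CNVR, `VST = (Vtotal - (Vpop1*Npop1 + Vpop2*Npop2)/Ntotal) /
#' Vtotal`, where `Vtotal` is the variance of copy number across all samples
#' pooled and `Vpop1`/`Vpop2` the within-population variances. Requires
#' exactly two populations.
#'
#' Variances use the population (denominator `N`) convention by default:
#' under it the sample-size-weighted within-group variances decompose the
#' total sum of squares exactly, so VST is the between-group variance
#' fraction, analogous to FST. `denominator = "N-1"` is offered for
#' sensitivity analysis.
#'
#' A CNVR with no copy-number variation at all (`Vtotal = 0`) carries no
#' differentiation signal: its VST is defined as 0 and flagged `degenerate`.
#' Values outside `[0, 1]` (possible only under the `N-1` convention) are
#' clamped, flagged, and reported via a message.
#'
#' @param x A [CNVRExperiment-class] from [buildCNMatrix()].
#' @param denominator `"N"` (population variance, default) or `"N-1"`.
#' @return A [S4Vectors::DataFrame] with one row per CNVR: `cnvr_id`, `vst`,
#'   `v_total`, `v_pop1`, `v_pop2`, `n_pop1`, `n_pop2`, `degenerate`,
#'   `clamped`. The population-to-label mapping is stored in
#'   `metadata(result)$populations`.
#' @examples
#' # pop1 = (2,2,4,4), pop2 = (2,2,2,2)  =>  VST = 1/3
#' @export
computeVst <- function(x, denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  m <- cnMatrix(x)
  pop <- populations(x)
  labs <- unique(pop)
  if (length(labs) != 2L)
    stop("VST requires exactly 2 populations, found ", length(labs), ": ",
         paste(labs, collapse = ", "))
  i1 <- which(pop == labs[1L]); i2 <- which(pop == labs[2L])
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("each population needs at least one sample")
  popvar <- function(mm, adj) {
    v <- rowMeans(mm^2) - rowMeans(mm)^2
    v <- pmax(v, 0)                    # guard tiny negative from roundoff
    if (denominator == "N-1") v * adj else v
  }
  v1 <- popvar(m[, i1, drop = FALSE], n1 / max(n1 - 1L, 1L))
  v2 <- popvar(m[, i2, drop = FALSE], n2 / max(n2 - 1L, 1L))
  vt <- popvar(m, n / (n - 1L))
  degenerate <- vt <= 1e-12
  within <- (v1 * n1 + v2 * n2) / n
  vst <- ifelse(degenerate, 0, (vt - within) / ifelse(degenerate, 1, vt))
  clamped <- !degenerate & (vst < 0 | vst > 1)
  if (any(clamped))
    message(sum(clamped), " VST value(s) clamped into [0, 1]")
  vst <- pmin(pmax(vst, 0), 1)
  out <- S4Vectors::DataFrame(
    cnvr_id = rownames(m), vst = unname(vst),
    v_total = unname(vt), v_pop1 = unname(v1), v_pop2 = unname(v2),
    n_pop1 = n1, n_pop2 = n2,
    degenerate = unname(degenerate), clamped = unname(clamped))
  S4Vectors::metadata(out)$populations <- stats::setNames(labs, c("pop1", "pop2"))
  out
}

#' Flag top-percentile VST records
#'
#' Selection follows the nearest-rank quantile: for fraction `f`, the
#' threshold is the VST value at rank `ceiling((1 - f) * M)` among the `M`
#' sorted values, and every record with `vst >= threshold` is selected, so
#' ties at the threshold are all included.
#'
#' @param records The `DataFrame` from [computeVst()].
#' @param fractions Upper-tail fractions; the defaults flag the top 10% and
#'   top 1%.
#' @return `records` with one added logical column per fraction (`top10`,
#'   `top1`, ... named `top<percent>`); the thresholds are stored in
#'   `metadata(records)$vst_thresholds`.
#' @export
selectTop <- function(records, fractions = c(0.10, 0.01)) {
  stopifnot(all(fractions > 0 & fractions < 1))
  v <- records$vst
  if (!sum(!is.na(v))) stop("no finite VST values")
  if (all(records$degenerate)) {
    warning("all VST values are degenerate; nothing selected")
    thr <- stats::setNames(rep(NA_real_, length(fractions)),
                           sprintf("top%g", fractions * 100))
    for (nm in names(thr)) records[[nm]] <- FALSE
    S4Vectors::metadata(records)$vst_thresholds <- thr
    return(records)
  }
  sorted <- sort(v[!is.na(v)])
  M <- length(sorted)
  thr <- vapply(fractions, function(f) sorted[ceiling((1 - f) * M)], 0)
  names(thr) <- sprintf("top%g", fractions * 100)
  for (k in seq_along(fractions))
    records[[names(thr)[k]]] <- !is.na(v) & v >= thr[k]
  S4Vectors::metadata(records)$vst_thresholds <- thr
  records
}
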