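#' PCA of samples on the copy-number matrix
#'
#' Column-centers the sample-by-CNVR matrix and factors it by singular value
#' decomposition. Component `i` explains `d_i^2 / sum(d^2)` of the variance.
#' The sign of each component is fixed by making its largest-magnitude CNVR
#' loading positive, so results are reproducible across platforms.
#'
#' @param x A [CNVRExperiment-class].
#' @param nComponents Number of components to return (default: all,
#'   `min(nSamples - 1, nCNVRs)`).
#' @return A list: `coordinates` (samples x components), `varianceExplained`
#'   (per component; all `NA`, with a warning, when the matrix is constant),
#'   and `loadings` (CNVRs x components).
#' @export
cnvPca <- function(x, nComponents = NULL) {
  m <- t(cnMatrix(x))                   # samples x CNVRs
  if (nrow(m) < 2L) stop("PCA needs at least 2 samples")
  mc <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(mc)
  total <- sum(sv$d^2)
  k <- min(nrow(m) - 1L, ncol(m))
  if (!is.null(nComponents)) k <- min(k, nComponents)
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                     # deterministic sign convention
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  coords <- u %*% diag(d, nrow = k)
  dimnames(coords) <- list(rownames(m), paste0("PC", seq_len(k)))
  dimnames(v) <- list(colnames(m), paste0("PC", seq_len(k)))
  if (total <= 1e-12) {
    warning("constant copy-number matrix: variance explained undefined")
    ve <- rep(NA_real_, k)
  } else ve <- d^2 / total
  list(coordinates = coords,
       varianceExplained = stats::setNames(ve, paste0("PC", seq_len(k))),
       loadings = v)
}

#' UPGMA tree of samples from copy-number distances
#'
#' Agglomerates the pairwise sample distance matrix by unweighted average
#' linkage (UPGMA), giving an ultrametric tree that displays sample
#' clustering; with two diverged populations the expectation is one cluster
#' per population. Samples are processed in lexicographic id order so that
#' distance ties break deterministically.
#'
#' @param x A [CNVRExperiment-class], or a `dist` over samples.
#' @param metric Distance metric passed to [stats::dist()] (ignored when `x`
#'   is already a `dist`).
#' @return An [ape] `phylo` tree whose tips are the sample ids; write it with
#'   `ape::write.tree()` for Newick output.
#' @export
upgmaTree <- function(x, metric = "euclidean") {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    m <- t(cnMatrix(x))
    if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
    m <- m[order(rownames(m)), , drop = FALSE]
    d <- stats::dist(m, method = metric)
  }
  if (attr(d, "Size") < 2L) stop("need at least 2 samples")
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}
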