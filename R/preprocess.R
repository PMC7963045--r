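# Preprocessing: variance-stabilizing transforms, scRNA-seq cell filters,
# highly-variable-gene selection, and PCA reduction.

#' Inverse-hyperbolic-sine transform
#'
#' Replaces every value x by \code{asinh(x / cofactor)}. The customary
#' cofactors are 150 for fluorescence (flow) cytometry and 5 for mass
#' cytometry.
#'
#' @param d a [JsomDataset-class].
#' @param cofactor positive scale divisor (default 150).
#' @return A transformed [JsomDataset-class]; names, labels and batches are
#'   unchanged.
#' @examples
#' d <- jsomDataset(matrix(c(0, 150), 1, 2))
#' values(arcsinhTransform(d))  # 0 and asinh(1)
#' @export
arcsinhTransform <- function(d, cofactor = 150) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("'cofactor' must be a positive scalar")
  jsomDataset(asinh(values(d) / cofactor), labels = cellLabels(d),
              batch = cellBatch(d))
}

#' Shifted-log transform
#'
#' Replaces every non-negative value x by \code{log(1 + x)}, the standard
#' transform for scRNA-seq count data.
#'
#' @param d a [JsomDataset-class] with non-negative values.
#' @return A transformed [JsomDataset-class].
#' @export
log1pTransform <- function(d) {
  if (any(values(d) < 0)) stop("log1p transform requires non-negative values")
  jsomDataset(log1p(values(d)), labels = cellLabels(d), batch = cellBatch(d))
}

#' Quality-control cell filtering for count data
#'
#' Keeps cells whose number of detected features (count > 0) lies within
#' \code{[minGenes, maxGenes]} and whose mitochondrial fraction of total
#' counts is at most \code{maxMitoFrac}. The bounds are inclusive: exclusion
#' is strictly "over \code{maxGenes}", "less than \code{minGenes}" and
#' "greater than \code{maxMitoFrac}". Cells with zero total counts have an
#' undefined mitochondrial fraction and are excluded with a warning.
#'
#' @param d a [JsomDataset-class] of raw non-negative counts.
#' @param mitoPrefix feature-name prefix marking mitochondrial genes
#'   (default \code{"MT-"}).
#' @param minGenes,maxGenes detected-gene bounds (defaults 200 and 2500).
#' @param maxMitoFrac maximum mitochondrial count fraction (default 0.05).
#' @return The filtered [JsomDataset-class] (a subset of the input cells).
#' @export
filterCells <- function(d, mitoPrefix = "MT-", minGenes = 200, maxGenes = 2500,
                        maxMitoFrac = 0.05) {
  v <- values(d)
  if (any(v < 0)) stop("filterCells expects non-negative counts")
  detected <- rowSums(v > 0)
  total <- rowSums(v)
  mito <- startsWith(featureNames(d), mitoPrefix)
  mitoCounts <- if (any(mito)) rowSums(v[, mito, drop = FALSE]) else numeric(nrow(v))
  zero <- total == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero total counts excluded")
  frac <- ifelse(zero, Inf, mitoCounts / total)
  keep <- !zero & detected >= minGenes & detected <= maxGenes & frac <= maxMitoFrac
  subsetCells(d, keep)
}

#' Highly variable features by variance-to-mean dispersion
#'
#' Scores each feature by its dispersion, the ratio of its (population)
#' variance to its mean across cells; features with mean 0 get dispersion 0.
#' Returns the indices of the \code{nTop} most dispersed features, ties broken
#' by the lower index.
#'
#' @param d a [JsomDataset-class] of non-negative values.
#' @param nTop number of features to select.
#' @return Integer vector of \code{nTop} feature column indices.
#' @export
selectHVG <- function(d, nTop) {
  if (nTop <= 0) stop("'nTop' must be positive")
  if (nTop > nFeatures(d)) stop("'nTop' exceeds the number of features")
  v <- values(d)
  mu <- colMeans(v)
  varp <- colMeans(v^2) - mu^2  # population variance
  disp <- ifelse(mu == 0, 0, varp / mu)
  order(-disp)[seq_len(nTop)]  # order() breaks ties by index
}

#' PCA reduction of a dataset
#'
#' Centers the features (optionally unit-scales them) and projects the cells
#' onto the top principal axes. The returned dataset's features are named
#' \code{PC1..PCk}; labels and batches are carried over.
#'
#' @param d a [JsomDataset-class].
#' @param nComponents number of components to keep; must not exceed
#'   \code{min(nCells, nFeatures)}.
#' @param scale unit-scale features before projection (default FALSE).
#' @return A [JsomDataset-class] of PCA scores [cells x nComponents].
#' @export
pcaReduce <- function(d, nComponents, scale = FALSE) {
  v <- values(d)
  if (nComponents > min(dim(v)))
    stop("'nComponents' exceeds min(nCells, nFeatures)")
  if (scale) {
    sds <- apply(v, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("constant features excluded from scaled PCA")
      v <- v[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = scale, rank. = nComponents)
  scores <- pc$x[, seq_len(nComponents), drop = FALSE]
  jsomDataset(scores, labels = cellLabels(d), batch = cellBatch(d),
              cellIds = cellIds(d),
              featureNames = paste0("PC", seq_len(nComponents)))
}
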