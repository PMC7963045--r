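# Synthetic paired datasets: two modalities observing a common set of
# Gaussian cell clusters through overlapping shared features (correlated
# across the datasets, up to a per-feature affine distortion emulating
# cross-technology scale differences) plus modality-private features. This is
# the minimal structure exercising every stage of the alignment pipeline:
# correlation matching, delta weighting, joint training, superposition
# clustering and label transfer. It deliberately omits count noise (negative
# binomial, dropout): values emulate post-preprocessing (transformed /
# PCA-reduced) inputs.

#' Simulation specification for paired synthetic datasets
#'
#' @param kClusters number of cell clusters common to both modalities
#'   (default 5).
#' @param cellsPerCluster cells per cluster, recycled across clusters; one
#'   number or a vector per cluster. Used for both datasets unless
#'   \code{cellsPerCluster2} is given (default 500).
#' @param cellsPerCluster2 optional per-cluster counts for dataset 2.
#' @param pShared number of shared features (default 8).
#' @param pPrivate1,pPrivate2 modality-private feature counts (default 4 each).
#' @param clusterSep minimum distance between cluster centers in shared
#'   space, in units of the noise SD (default 6: well separated).
#' @param noiseSd within-cluster Gaussian noise SD (default 1).
#' @param sharedDistortion SD of the per-feature affine perturbation
#'   (slope ~ 1 + N(0, sd), intercept ~ N(0, sd)) applied to dataset 2's
#'   shared coordinates (default 0.05).
#' @param missingClusterInD2 optional cluster index (1-based) omitted from
#'   dataset 2, emulating a population present in only one modality.
#' @param seed integer seed.
#' @return A list of class \code{simSpec}.
#' @export
simSpec <- function(kClusters = 5, cellsPerCluster = 500,
                    cellsPerCluster2 = NULL, pShared = 8, pPrivate1 = 4,
                    pPrivate2 = 4, clusterSep = 6, noiseSd = 1,
                    sharedDistortion = 0.05, missingClusterInD2 = NULL,
                    seed = 1L) {
  if (kClusters < 2) stop("'kClusters' must be >= 2")
  if (clusterSep <= 0) stop("'clusterSep' must be positive")
  cells1 <- rep_len(cellsPerCluster, kClusters)
  cells2 <- rep_len(if (is.null(cellsPerCluster2)) cellsPerCluster
                    else cellsPerCluster2, kClusters)
  if (any(c(cells1, cells2) < 1)) stop("cell counts must be >= 1")
  if (!is.null(missingClusterInD2) &&
      (missingClusterInD2 < 1 || missingClusterInD2 > kClusters))
    stop("'missingClusterInD2' out of range")
  structure(list(kClusters = as.integer(kClusters), cells1 = as.integer(cells1),
                 cells2 = as.integer(cells2), pShared = as.integer(pShared),
                 pPrivate1 = as.integer(pPrivate1),
                 pPrivate2 = as.integer(pPrivate2),
                 clusterSep = clusterSep, noiseSd = noiseSd,
                 sharedDistortion = sharedDistortion,
                 missingClusterInD2 = missingClusterInD2,
                 seed = as.integer(seed)),
            class = "simSpec")
}

.drawCenters <- function(k, p, minSep, maxTries = 2000L) {
  centers <- matrix(NA_real_, k, p)
  centers[1L, ] <- stats::rnorm(p, sd = minSep)
  for (i in seq_len(k)[-1L]) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cand <- stats::rnorm(p, sd = minSep)
      dmin <- min(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                  rep(cand, each = i - 1L))^2)))
      if (dmin >= minSep) { centers[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not place separated cluster centers; ",
                  "lower kClusters or clusterSep")
  }
  centers
}

#' Generate a pair of synthetic datasets with known cluster structure
#'
#' Draws \code{kClusters} cluster centers in the shared feature space with
#' pairwise separation at least \code{clusterSep * noiseSd}, plus private
#' centers per modality at the same scale. Dataset 1 cells are
#' center + Gaussian noise over [shared | private1] features; dataset 2 cells
#' likewise over [shared | private2], with the shared coordinates passed
#' through an independent per-feature affine map \code{a*x + b} to emulate
#' cross-technology differences in scale and offset. The shared features
#' occupy the first \code{pShared} columns of both datasets (see the
#' \code{shared} element of the result).
#'
#' @param spec a [simSpec()].
#' @return A list with [JsomDataset-class] elements \code{d1} and \code{d2}
#'   (cluster memberships in their \code{labels}), and \code{shared}, the
#'   [SharedFeatures-class] correspondence.
#' @examples
#' sim <- generatePaired(simSpec(kClusters = 3, cellsPerCluster = 20, seed = 7))
#' table(cellLabels(sim$d1))
#' @export
generatePaired <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  withSeed(spec$seed, {
    k <- spec$kClusters
    sep <- spec$clusterSep * spec$noiseSd
    centersS <- .drawCenters(k, spec$pShared, sep)
    centersP1 <- matrix(stats::rnorm(k * spec$pPrivate1, sd = sep), k)
    centersP2 <- matrix(stats::rnorm(k * spec$pPrivate2, sd = sep), k)
    slope <- 1 + stats::rnorm(spec$pShared, sd = spec$sharedDistortion)
    intercept <- stats::rnorm(spec$pShared, sd = spec$sharedDistortion)

    drawDataset <- function(cells, centersP, distort) {
      clu <- rep(seq_len(k), cells)
      ncell <- length(clu)
      p <- spec$pShared + ncol(centersP)
      X <- cbind(centersS, centersP)[clu, , drop = FALSE] +
        matrix(stats::rnorm(ncell * p, sd = spec$noiseSd), ncell)
      if (distort) {
        sh <- seq_len(spec$pShared)
        X[, sh] <- sweep(sweep(X[, sh, drop = FALSE], 2L, slope, "*"),
                         2L, intercept, "+")
      }
      list(X = X, labels = paste0("cluster", clu))
    }
    a <- drawDataset(spec$cells1, centersP1, distort = FALSE)
    cells2 <- spec$cells2
    if (!is.null(spec$missingClusterInD2)) cells2[spec$missingClusterInD2] <- 0L
    b <- drawDataset(cells2, centersP2, distort = TRUE)

    fnames <- function(pPriv, tag) c(paste0("shared_", seq_len(spec$pShared)),
                                     if (pPriv) paste0("private_", tag, "_",
                                                       seq_len(pPriv)))
    d1 <- jsomDataset(a$X, labels = a$labels, batch = rep("d1", nrow(a$X)),
                      cellIds = paste0("c1_", seq_len(nrow(a$X))),
                      featureNames = fnames(spec$pPrivate1, "1"))
    d2 <- jsomDataset(b$X, labels = b$labels, batch = rep("d2", nrow(b$X)),
                      cellIds = paste0("c2_", seq_len(nrow(b$X))),
                      featureNames = fnames(spec$pPrivate2, "2"))
    list(d1 = d1, d2 = d2,
         shared = sharedFeatures(seq_len(spec$pShared), seq_len(spec$pShared)))
  })
}
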