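# Density-dependent downsampling: cap the training-set size while equalizing
# the representation of rare and abundant populations. Cells in dense regions
# are kept with probability inversely proportional to their local density, so
# a small population survives the cap nearly intact.

#' Local density profile of a dataset
#'
#' The kernel radius is \code{radiusMultiplier} times the median over cells of
#' the distance to their nearest other cell; the local density of a cell is
#' the number of cells (itself included) within that radius. Distances are
#' exact Euclidean, computed in row blocks to bound memory.
#'
#' @param values numeric matrix [cells x features], at least 2 cells.
#' @param radiusMultiplier positive multiplier of the median nearest-neighbor
#'   distance (default 5).
#' @param block rows per distance block.
#' @return A list with \code{localDensity} (integer vector, >= 1) and
#'   \code{kernelRadius}.
#' @export
localDensity <- function(values, radiusMultiplier = 5, block = 1024L) {
  values <- as.matrix(values)
  ncell <- nrow(values)
  if (ncell < 2L) stop("need at least 2 cells")
  if (radiusMultiplier <= 0) stop("'radiusMultiplier' must be positive")
  sq <- rowSums(values^2)
  nn <- numeric(ncell)
  blockD2 <- function(idx) {
    d2 <- outer(sq[idx], sq, "+") - 2 * values[idx, , drop = FALSE] %*% t(values)
    d2[d2 < 0] <- 0
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self for NN distance
    d2
  }
  starts <- seq(1L, ncell, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1L, ncell)
    nn[idx] <- sqrt(apply(blockD2(idx), 1L, min))
  }
  radius <- radiusMultiplier * stats::median(nn)
  if (radius == 0)
    warning("kernel radius is 0 (most cells have exact duplicates); ",
            "only coincident cells count as neighbors")
  dens <- integer(ncell)
  r2 <- radius^2
  for (s in starts) {
    idx <- s:min(s + block - 1L, ncell)
    d2 <- blockD2(idx)
    dens[idx] <- rowSums(d2 <= r2) + 1L  # self back in
  }
  list(localDensity = dens, kernelRadius = radius)
}

#' Density-dependent downsampling to a target size
#'
#' Computes the [localDensity()] profile, discards outlier cells whose density
#' falls below the \code{outlierPercentile} percentile, then finds (by
#' bisection) the largest target density TD such that the expected kept count
#' \code{sum(pmin(1, TD / density))} does not exceed \code{targetSize}, and
#' keeps each remaining cell independently with probability
#' \code{min(1, TD / density)}. Rare (low-density) populations are therefore
#' retained at a much higher rate than abundant ones. Datasets at or under
#' the target are returned unchanged, consuming no randomness.
#'
#' @param values numeric matrix [cells x features].
#' @param targetSize desired number of kept cells (default 10000).
#' @param outlierPercentile density percentile treated as outliers
#'   (default 1; 0 disables outlier removal).
#' @param seed integer seed for the keep draws.
#' @param radiusMultiplier passed to [localDensity()].
#' @return Sorted integer vector of kept cell indices.
#' @export
densityDownsample <- function(values, targetSize = 10000, outlierPercentile = 1,
                              seed = 1L, radiusMultiplier = 5) {
  values <- as.matrix(values)
  ncell <- nrow(values)
  if (targetSize < 1) stop("'targetSize' must be >= 1")
  if (outlierPercentile < 0 || outlierPercentile >= 50)
    stop("'outlierPercentile' must be in [0, 50)")
  if (ncell <= targetSize) return(seq_len(ncell))
  dens <- localDensity(values, radiusMultiplier = radiusMultiplier)$localDensity
  candidates <- seq_len(ncell)
  if (outlierPercentile > 0) {
    cut <- stats::quantile(dens, outlierPercentile / 100)
    candidates <- candidates[dens >= cut]
  }
  dc <- dens[candidates]
  expectedKeep <- function(td) sum(pmin(1, td / dc))
  if (expectedKeep(max(dc)) <= targetSize) {
    td <- max(dc)  # even keeping everything stays under target
  } else {
    lo <- 0; hi <- max(dc)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (expectedKeep(mid) <= targetSize) lo <- mid else hi <- mid
    }
    td <- lo
  }
  u <- withSeed(seed, stats::runif(length(dc)))
  candidates[u < pmin(1, td / dc)]
}

#' Uniform random downsampling
#'
#' Plain random sampling without replacement to \code{targetSize}; used when
#' density-dependent downsampling is disabled but a dataset exceeds the
#' training cap.
#'
#' @inheritParams densityDownsample
#' @return Sorted integer vector of kept cell indices.
#' @export
uniformDownsample <- function(values, targetSize = 10000, seed = 1L) {
  ncell <- nrow(as.matrix(values))
  if (ncell <= targetSize) return(seq_len(ncell))
  withSeed(seed, sort(sample.int(ncell, targetSize)))
}
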