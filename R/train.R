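# Coupled-map training. Two self-organizing maps share one grid; every
# iteration performs the classical (independent) update of each map with a
# drawn data point, then a joint update that pushes the OTHER map's codebook,
# at the same node neighborhood, toward the drawn point's matched partner,
# weighted by the matching weight delta. The coupling drags related clusters
# of the two datasets onto the same grid region.
#
# Randomness protocol (given config@seed): (1) codebook initialization, V1
# then V2, column by column; (2) the per-epoch sampling permutations, dataset
# 1 first then dataset 2. The update loop itself consumes no randomness, so
# a run is fully reproducible from the seed.

.initMaps <- function(config, X1, X2) {
  k <- config@m * config@n
  drawV <- function(X) {
    V <- matrix(0, k, ncol(X))
    for (j in seq_len(ncol(X)))
      V[, j] <- stats::runif(k, min(X[, j]), max(X[, j]))
    V
  }
  new("JsomMap", m = config@m, n = config@n,
      V1 = drawV(X1), V2 = drawV(X2), config = config)
}

.drawSequence <- function(ncell, total, sampling) {
  if (sampling == "iid") return(sample.int(ncell, total, replace = TRUE))
  reps <- ceiling(total / ncell)
  idx <- unlist(lapply(seq_len(reps), function(e) sample.int(ncell)))
  idx[seq_len(total)]
}

#' Random codebook initialization
#'
#' Fills both codebook matrices with seeded uniform draws, each component
#' within its feature's observed [min, max] range in the corresponding
#' dataset.
#'
#' @param config a [JsomConfig-class].
#' @param d1,d2 non-empty [JsomDataset-class] objects.
#' @param seed seed for the draws (default the config seed).
#' @return An untrained [JsomMap-class].
#' @export
initializeMaps <- function(config, d1, d2, seed = config@seed) {
  if (nCells(d1) < 1L || nCells(d2) < 1L) stop("datasets must be non-empty")
  withSeed(seed, .initMaps(config, values(d1), values(d2)))
}

#' Learning-rate and neighborhood-radius schedule
#'
#' Both parameters decay linearly over the training run: the learning rate
#' from \code{alpha0} at iteration 0 to \code{alphaFinal} at iteration T-1,
#' and the radius from \code{epsilon0} to 0. Once the radius drops below 1
#' only the best-matching unit is updated. With fewer than two iterations the
#' initial values are returned.
#'
#' @param config a [JsomConfig-class].
#' @param t 0-based iteration index, \code{0 <= t < T}.
#' @param T total number of iterations.
#' @return Named numeric vector \code{c(alpha =, epsilon =)}.
#' @examples
#' cfg <- jsomConfig()
#' schedule(cfg, 0, 100)   # c(0.9, 6)
#' schedule(cfg, 99, 100)  # c(0.01, 0)
#' @export
schedule <- function(config, t, T) {
  if (T < 2) return(c(alpha = config@alpha0, epsilon = config@epsilon0))
  frac <- t / (T - 1)
  if (frac >= 1) return(c(alpha = config@alphaFinal, epsilon = 0))
  alpha <- config@alpha0 + (config@alphaFinal - config@alpha0) * frac
  eps <- config@epsilon0 * (1 - frac)
  c(alpha = max(config@alphaFinal, alpha), epsilon = max(0, eps))
}

#' Apply one codebook update
#'
#' Moves the codebook vectors of the given nodes a fraction
#' \code{delta * alpha} of the way toward the data point x:
#' \code{V[j, ] <- V[j, ] + delta * alpha * (x - V[j, ])}. All other rows are
#' untouched. Since \code{delta * alpha} lies in [0, 1] each update is a
#' convex combination, so codebook components never leave the range spanned
#' by the data and the initialization.
#'
#' @param V numeric codebook matrix [nodes x d].
#' @param nodes integer vector of 1-based node indices to update.
#' @param x numeric data point of length d.
#' @param delta matching weight in [-1, 1] (negative only when negative
#'   correlations are explicitly retained).
#' @param alpha learning rate in (0, 1].
#' @return The updated codebook matrix.
#' @export
applyUpdate <- function(V, nodes, x, delta, alpha) {
  if (length(x) != ncol(V)) stop("dimension mismatch between 'x' and 'V'")
  if (delta == 0 || !length(nodes)) return(V)
  step <- delta * alpha
  Vn <- V[nodes, , drop = FALSE]
  V[nodes, ] <- Vn + step * (rep(x, each = length(nodes)) - Vn)
  V
}

#' Train the coupled maps
#'
#' Runs \code{T = epochs * max(n1, n2)} iterations. Each iteration draws one
#' point from each dataset (a per-epoch random permutation by default, so
#' every point of the larger dataset is used exactly \code{epochs} times),
#' performs the two independent updates at each point's best-matching unit
#' and its grid neighborhood, then the two joint updates: the node set
#' updated for the dataset-1 point also pulls map 2 toward that point's
#' matched dataset-2 partner with weight \code{delta1}, and symmetrically for
#' the dataset-2 point. The learning rate and radius follow [schedule()].
#'
#' The matching must have been computed on exactly the rows of \code{d1} and
#' \code{d2} supplied here (downsample first, then match); [runJsom()] wires
#' the full pipeline correctly.
#'
#' @param d1,d2 [JsomDataset-class] training data (already downsampled if
#'   desired).
#' @param matching a [JsomMatching-class] over the same rows.
#' @param config a [JsomConfig-class]; its \code{joint},
#'   \code{deltaInIndependent} and \code{sampling} switches control the loop.
#' @return The trained [JsomMap-class].
#' @export
trainJsom <- function(d1, d2, matching, config) {
  X1 <- values(d1); X2 <- values(d2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (length(matching@match1to2) != n1 || length(matching@match2to1) != n2)
    stop("matching size does not agree with the training datasets")
  if (max(matching@match1to2) > n2 || max(matching@match2to1) > n1)
    stop("matching indices out of range for the training datasets")
  total <- config@epochs * max(n1, n2)
  coords <- gridCoordinates(config@m, config@n)

  state <- withSeed(config@seed, {
    maps <- .initMaps(config, X1, X2)
    seq1 <- .drawSequence(n1, total, config@sampling)
    seq2 <- .drawSequence(n2, total, config@sampling)
    list(maps = maps, seq1 = seq1, seq2 = seq2)
  })
  V1 <- state$maps@V1; V2 <- state$maps@V2
  d1ind <- matching@delta1; d2ind <- matching@delta2
  if (!config@deltaInIndependent) {
    d1ind <- rep(1, n1); d2ind <- rep(1, n2)
  }

  for (t in seq_len(total)) {
    sch <- schedule(config, t - 1L, total)
    a <- sch[[1L]]; eps <- sch[[2L]]
    i1 <- state$seq1[t]; i2 <- state$seq2[t]
    x1 <- X1[i1, ]; x2 <- X2[i2, ]

    b1 <- findBMU(x1, V1)
    nb1 <- gridNeighborhood(b1, eps, coords = coords)
    V1 <- applyUpdate(V1, nb1, x1, d1ind[i1], a)
    b2 <- findBMU(x2, V2)
    nb2 <- gridNeighborhood(b2, eps, coords = coords)
    V2 <- applyUpdate(V2, nb2, x2, d2ind[i2], a)

    if (config@joint) {
      V2 <- applyUpdate(V2, nb1, X2[matching@match1to2[i1], ],
                        matching@delta1[i1], a)
      V1 <- applyUpdate(V1, nb2, X1[matching@match2to1[i2], ],
                        matching@delta2[i2], a)
    }
  }
  new("JsomMap", m = config@m, n = config@n, V1 = V1, V2 = V2, config = config)
}

#' Quantization error of a dataset on a codebook
#'
#' Mean Euclidean distance of each row of \code{values} to its best-matching
#' codebook vector; a standard summary of how faithfully a trained map
#' represents its dataset.
#'
#' @param values numeric matrix [cells x d].
#' @param V codebook matrix [nodes x d].
#' @return Non-negative scalar.
#' @export
quantizationError <- function(values, V) {
  values <- as.matrix(values)
  sqV <- rowSums(V^2)
  d2 <- outer(rowSums(values^2), sqV, "+") - 2 * values %*% t(V)
  mean(sqrt(pmax(0, apply(d2, 1L, min))))
}
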