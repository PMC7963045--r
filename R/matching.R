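# Cross-dataset matching on shared features: Pearson-correlation mode and
# binarized ('binary') mode built on a two-segment step fit per feature.

#' Pearson-correlation matching of two shared-feature matrices
#'
#' For each row (cell) of \code{sharedA}, finds the row of \code{sharedB} with
#' the highest Pearson correlation across the p shared features, and
#' symmetrically for the other direction. The matching weight delta is the
#' best correlation, clamped at 0 by default: a negative weight would push
#' codebook vectors away from the data during training.
#'
#' Cells with zero variance across the shared features have undefined
#' correlation; they are matched to row 1 with delta 0 and a warning.
#'
#' @param sharedA,sharedB numeric matrices [cells x p] over the same p shared
#'   features in the same order.
#' @param allowNegative keep negative correlations as deltas (default FALSE).
#' @param block number of rows of \code{sharedA}/\code{sharedB} correlated per
#'   block, bounding the score-matrix memory.
#' @return A [JsomMatching-class] with mode \code{"correlation"}.
#' @examples
#' A <- matrix(rnorm(30), 10, 3)
#' m <- pearsonMatch(A, A)
#' all(matchIndices(m) == 1:10)
#' @export
pearsonMatch <- function(sharedA, sharedB, allowNegative = FALSE, block = 4096L) {
  sharedA <- as.matrix(sharedA); sharedB <- as.matrix(sharedB)
  p <- ncol(sharedA)
  if (ncol(sharedB) != p) stop("shared matrices must have the same column count")
  if (p < 3) warning("fewer than 3 shared features; correlations will be unstable")
  nA <- nrow(sharedA); nB <- nrow(sharedB)
  constA <- apply(sharedA, 1L, stats::sd) == 0
  constB <- apply(sharedB, 1L, stats::sd) == 0
  if (any(constA) || any(constB))
    warning("constant rows across shared features: correlation undefined, delta set to 0")

  m12 <- integer(nA); d1 <- numeric(nA)
  m21 <- rep(1L, nB); d2 <- rep(-Inf, nB)
  tB <- t(sharedB)
  for (start in seq(1L, nA, by = block)) {
    idx <- start:min(start + block - 1L, nA)
    C <- suppressWarnings(stats::cor(t(sharedA[idx, , drop = FALSE]), tB))
    C[is.na(C)] <- -Inf
    m12[idx] <- max.col(C, ties.method = "first")
    d1[idx] <- C[cbind(seq_along(idx), m12[idx])]
    # fold the block into the reverse direction (ties -> lowest A index, so
    # only strict improvements overwrite)
    bestB <- apply(C, 2L, which.max)
    valB <- C[cbind(bestB, seq_len(nB))]
    better <- valB > d2
    m21[better] <- idx[bestB[better]]
    d2[better] <- valB[better]
  }
  d1[!is.finite(d1)] <- 0; d2[!is.finite(d2)] <- 0
  m12[m12 < 1L] <- 1L
  m12[constA] <- 1L; d1[constA] <- 0
  d2[constB] <- 0; m21[constB] <- 1L
  if (!allowNegative) { d1 <- pmax(0, d1); d2 <- pmax(0, d2) }
  d1 <- pmin(1, d1); d2 <- pmin(1, d2)
  new("JsomMatching", match1to2 = as.integer(m12), match2to1 = as.integer(m21),
      delta1 = d1, delta2 = d2, mode = "correlation")
}

#' Two-segment step-fit threshold for one feature
#'
#' Sorts the values ascending and fits, at every split point s in 1..(len-1),
#' the piecewise-constant function taking the left-segment mean on the first s
#' values and the right-segment mean on the rest. The split minimizing the
#' total squared error is chosen (ties: smallest s) and the threshold is the
#' midpoint of the two segment means. Computed with prefix sums in O(len).
#'
#' @param x numeric vector, length >= 2, not all values identical.
#' @return A list with \code{threshold} (numeric) and \code{splitIndex}
#'   (integer s: the left segment holds the s smallest values).
#' @examples
#' stepminerThreshold(c(1, 1, 1, 5, 5, 5))  # threshold 3, split 3
#' @export
stepminerThreshold <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (max(x) == min(x))
    stop("degenerate input: all values identical, no step exists")
  xs <- sort(x)
  len <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  s <- seq_len(len - 1L)
  leftSum <- cs[s];          leftSq <- cs2[s]
  rightSum <- cs[len] - leftSum; rightSq <- cs2[len] - leftSq
  nl <- s; nr <- len - s
  sse <- (leftSq - leftSum^2 / nl) + (rightSq - rightSum^2 / nr)
  best <- which.min(sse)
  list(threshold = (leftSum[best] / nl[best] + rightSum[best] / nr[best]) / 2,
       splitIndex = as.integer(best))
}

#' Binarize a shared-feature matrix by per-feature step thresholds
#'
#' Each column gets its own [stepminerThreshold()]; entries strictly above the
#' threshold become 1, others 0. Constant columns carry no step and are
#' dropped with a warning (callers pairing two datasets must drop the paired
#' column on the other side too; [buildMatching()] does this).
#'
#' @param shared numeric matrix [cells x p].
#' @return A list with \code{bits} (0/1 matrix over the kept columns),
#'   \code{thresholds} (numeric per kept column) and \code{kept} (integer
#'   indices of the kept columns of \code{shared}).
#' @export
binarizeDataset <- function(shared) {
  shared <- as.matrix(shared)
  constant <- apply(shared, 2L, function(v) max(v) == min(v))
  if (any(constant))
    warning(sum(constant), " constant shared feature(s) dropped before binarization")
  kept <- which(!constant)
  if (!length(kept)) stop("no non-constant shared features to binarize")
  thr <- vapply(kept, function(k) stepminerThreshold(shared[, k])$threshold,
                numeric(1))
  bits <- matrix(0L, nrow(shared), length(kept))
  for (i in seq_along(kept)) bits[, i] <- as.integer(shared[, kept[i]] > thr[i])
  list(bits = bits, thresholds = thr, kept = kept)
}

#' Binary matching of two binarized views
#'
#' The similarity between a cell of A and a cell of B is the fraction of
#' shared features on which their bits agree (both positive or both negative);
#' each cell is matched to the cell of the other dataset with the highest
#' agreement (ties: lowest index) and delta is that fraction.
#'
#' @param binA,binB binarized views from [binarizeDataset()] (or any lists
#'   with a 0/1 \code{bits} matrix); must have the same number of columns.
#' @return A [JsomMatching-class] with mode \code{"binary"}.
#' @export
binaryMatch <- function(binA, binB) {
  A <- binA$bits; B <- binB$bits
  p <- ncol(A)
  if (ncol(B) != p) stop("binarized views must have the same number of features")
  # agreements = A.B' + (1-A).(1-B)'
  agree <- A %*% t(B) + (1 - A) %*% t(1 - B)
  sim <- agree / p
  m12 <- max.col(sim, ties.method = "first")
  d1 <- sim[cbind(seq_len(nrow(A)), m12)]
  simT <- t(sim)
  m21 <- max.col(simT, ties.method = "first")
  d2 <- simT[cbind(seq_len(nrow(B)), m21)]
  new("JsomMatching", match1to2 = as.integer(m12), match2to1 = as.integer(m21),
      delta1 = d1, delta2 = d2, mode = "binary")
}

#' Build the cross-dataset matching from shared features
#'
#' Extracts the shared-feature submatrices of the two datasets in the order
#' given by \code{spec} and dispatches to [pearsonMatch()] (mode
#' \code{"correlation"}, the default) or to [binarizeDataset()] +
#' [binaryMatch()] (mode \code{"binary"}). In binary mode a shared feature
#' constant in either dataset is dropped from both, preserving the positional
#' correspondence.
#'
#' @param d1,d2 [JsomDataset-class] objects.
#' @param spec a [SharedFeatures-class] correspondence.
#' @param mode \code{"correlation"} or \code{"binary"}.
#' @param allowNegative passed to [pearsonMatch()].
#' @return A [JsomMatching-class].
#' @examples
#' d <- jsomDataset(matrix(rnorm(40), 10, 4))
#' sf <- sharedFeatures(1:3, 1:3)
#' m <- buildMatching(d, d, sf)
#' all(matchWeights(m, 1) == 1)
#' @export
buildMatching <- function(d1, d2, spec, mode = c("correlation", "binary"),
                          allowNegative = FALSE) {
  mode <- match.arg(mode)
  i1 <- sharedIdx1(spec); i2 <- sharedIdx2(spec)
  if (any(i1 > nFeatures(d1)) || any(i2 > nFeatures(d2)))
    stop("shared feature index out of range")
  A <- values(d1)[, i1, drop = FALSE]
  B <- values(d2)[, i2, drop = FALSE]
  if (mode == "correlation") return(pearsonMatch(A, B, allowNegative = allowNegative))
  constA <- apply(A, 2L, function(v) max(v) == min(v))
  constB <- apply(B, 2L, function(v) max(v) == min(v))
  drop <- constA | constB
  if (any(drop)) {
    warning(sum(drop), " shared feature pair(s) dropped (constant in at least one dataset)")
    A <- A[, !drop, drop = FALSE]; B <- B[, !drop, drop = FALSE]
  }
  binaryMatch(binarizeDataset(A), binarizeDataset(B))
}
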