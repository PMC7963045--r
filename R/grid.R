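# Grid geometry and best-matching-unit search.
#
# Node indexing convention: nodes are numbered 1..m*n in row-major order and
# node j sits at 0-based grid coordinate (row, col) = ((j-1) %/% n, (j-1) %% n).
# Neighborhoods use the Euclidean metric on these integer coordinates.

#' Grid coordinates of a rectangular node map
#'
#' @param m,n positive grid dimensions (rows, columns).
#' @return An integer matrix with \code{m*n} rows and columns \code{row},
#'   \code{col}: node j (row-major, 1-based) has 0-based coordinates
#'   \code{((j-1) \%/\% n, (j-1) \%\% n)}.
#' @examples
#' gridCoordinates(2, 3)
#' @export
gridCoordinates <- function(m, n) {
  if (length(m) != 1L || length(n) != 1L || is.na(m) || is.na(n) ||
      m < 1 || n < 1 || m != round(m) || n != round(n))
    stop("'m' and 'n' must be positive integers")
  j <- seq_len(m * n) - 1L
  cbind(row = j %/% as.integer(n), col = j %% as.integer(n))
}

#' Nodes within a neighborhood radius on the grid
#'
#' Returns every node whose Euclidean distance (in grid coordinates) from the
#' center node is at most \code{epsilon}; the center is always included, so a
#' radius below 1 updates only the best-matching unit.
#'
#' @param center 1-based node index of the neighborhood center.
#' @param epsilon non-negative radius in grid units.
#' @param m,n grid dimensions.
#' @param coords optional precomputed [gridCoordinates()] matrix (performance).
#' @return Sorted integer vector of 1-based node indices.
#' @examples
#' gridNeighborhood(5, 1, 3, 3)  # center of a 3x3 grid + 4 edge neighbors
#' @export
gridNeighborhood <- function(center, epsilon, m, n, coords = NULL) {
  if (is.null(coords)) coords <- gridCoordinates(m, n)
  if (center < 1L || center > nrow(coords)) stop("'center' out of range")
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  d2 <- (coords[, 1L] - coords[center, 1L])^2 +
        (coords[, 2L] - coords[center, 2L])^2
  which(d2 <= epsilon^2)
}

#' Best-matching unit of a data point
#'
#' Index of the codebook row nearest (Euclidean) to \code{x}; ties are broken
#' by the lowest node index so runs are reproducible.
#'
#' @param x numeric vector of length \code{ncol(V)}.
#' @param V numeric codebook matrix, one row per node.
#' @return 1-based row index of the nearest codebook vector.
#' @examples
#' findBMU(c(1, 1), rbind(c(0, 0), c(10, 10)))
#' @export
findBMU <- function(x, V) {
  if (length(x) != ncol(V))
    stop("length of 'x' (", length(x), ") does not match ncol(V) (", ncol(V), ")")
  which.min(colSums((t(V) - x)^2))
}
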