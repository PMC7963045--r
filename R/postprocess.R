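# Post-training analysis: node assignment, mode maps, superposition
# clustering, composition tables, and label transfer.

#' Assign cells to their nearest nodes
#'
#' Every cell of dataset 1 is assigned to the node whose map-1 codebook vector
#' is nearest (Euclidean), and likewise dataset 2 on map 2. Assignment is run
#' on the full datasets, not only the cells retained for training.
#'
#' @param d1,d2 [JsomDataset-class] objects with the training feature spaces.
#' @param maps a trained [JsomMap-class].
#' @param block rows per distance block.
#' @return A [JsomAssignment-class].
#' @export
assignToNodes <- function(d1, d2, maps, block = 4096L) {
  assignOne <- function(X, V) {
    if (ncol(X) != ncol(V)) stop("feature dimension does not match the codebook")
    out <- integer(nrow(X))
    sqV <- rowSums(V^2)
    for (s in seq(1L, nrow(X), by = block)) {
      idx <- s:min(s + block - 1L, nrow(X))
      Xb <- X[idx, , drop = FALSE]
      d2m <- outer(rowSums(Xb^2), sqV, "+") - 2 * Xb %*% t(V)
      out[idx] <- max.col(-d2m, ties.method = "first")
    }
    out
  }
  new("JsomAssignment",
      nodes1 = assignOne(values(d1), maps@V1),
      nodes2 = assignOne(values(d2), maps@V2),
      nNodes = maps@m * maps@n)
}

#' Per-node majority labels (mode map)
#'
#' Tabulates the labels of the cells assigned to each node and reports the
#' majority label per node; ties go to the lexicographically smallest label
#' and unoccupied nodes are marked \code{NA}.
#'
#' @param nodes integer vector of 1-based node assignments.
#' @param labels character vector of cell labels, same length.
#' @param nNodes total number of nodes.
#' @return A list with \code{majority} (character vector of length
#'   \code{nNodes}, \code{NA} = empty node) and \code{counts} (integer matrix
#'   node x label).
#' @export
modeMap <- function(nodes, labels, nNodes) {
  if (length(nodes) != length(labels)) stop("'nodes' and 'labels' lengths differ")
  labs <- sort(unique(as.character(labels)))
  counts <- matrix(0L, nNodes, length(labs), dimnames = list(NULL, labs))
  tab <- table(factor(nodes, levels = seq_len(nNodes)),
               factor(as.character(labels), levels = labs))
  counts[] <- as.integer(tab)
  majority <- rep(NA_character_, nNodes)
  occupied <- rowSums(counts) > 0
  if (any(occupied))
    majority[occupied] <- labs[max.col(counts[occupied, , drop = FALSE],
                                       ties.method = "first")]
  list(majority = majority, counts = counts)
}

#' Superposition clustering of the nodes
#'
#' Concatenates each node's two codebook vectors into one row of
#' \code{[V1 | V2]} and clusters the nodes by agglomerative hierarchical
#' clustering with Ward's linkage on Euclidean distances, cutting the tree at
#' K clusters. Cluster ids are relabeled 1..K in order of first-occurring
#' node index.
#'
#' @param maps a trained [JsomMap-class].
#' @param K number of clusters; defaults to \code{max(m, n)}.
#' @return Integer vector of length \code{m*n} with values in 1..K, and
#'   attribute \code{K}.
#' @export
superposeCluster <- function(maps, K = max(gridDim(maps))) {
  nNodes <- maps@m * maps@n
  if (K < 1 || K > nNodes) stop("'K' must be between 1 and the number of nodes")
  hc <- stats::hclust(stats::dist(cbind(maps@V1, maps@V2)), method = "ward.D2")
  raw <- stats::cutree(hc, k = K)
  relabel <- match(raw, unique(raw))  # first-occurrence order
  structure(as.integer(relabel), K = as.integer(K))
}

#' Cluster-by-label composition table
#'
#' For each dataset with labels, reports for every (node cluster, label) pair
#' the percentage of that label's cells assigned to nodes of that cluster, so
#' each label column sums to 100.
#'
#' @param assignment a [JsomAssignment-class].
#' @param clustering per-node cluster labels from [superposeCluster()].
#' @param labels1,labels2 per-cell label vectors (either may be \code{NULL}).
#' @return A list with numeric matrices \code{dataset1} and/or
#'   \code{dataset2} [clusters x labels] of percentages.
#' @export
compositionTable <- function(assignment, clustering, labels1 = NULL,
                             labels2 = NULL) {
  K <- attr(clustering, "K")
  if (is.null(K)) K <- max(clustering)
  oneTable <- function(nodes, labels) {
    cellCluster <- clustering[nodes]
    tab <- table(factor(cellCluster, levels = seq_len(K)),
                 as.character(labels))
    sweep(unclass(tab), 2L, colSums(tab), function(a, b) 100 * a / b)
  }
  out <- list()
  if (!is.null(labels1)) out$dataset1 <- oneTable(nodes1(assignment), labels1)
  if (!is.null(labels2)) out$dataset2 <- oneTable(nodes2(assignment), labels2)
  if (!length(out)) stop("labels are required for at least one dataset")
  out
}

#' Transfer labels from a reference to a query dataset
#'
#' Builds the per-node majority labels of the labeled reference assignment
#' and gives each query cell its node's majority label. A query cell landing
#' on a node empty in the reference receives the label of the nearest
#' (grid-distance) non-empty node — ties to the lowest node index — and is
#' flagged as imputed.
#'
#' @param refNodes,refLabels node assignment and labels of the reference cells.
#' @param queryNodes node assignment of the query cells (same map geometry).
#' @param m,n grid dimensions.
#' @return A data.frame with columns \code{label} and \code{imputed}.
#' @export
transferLabels <- function(refNodes, refLabels, queryNodes, m, n) {
  nNodes <- m * n
  if (!length(refNodes)) stop("reference assignment is empty")
  mm <- modeMap(refNodes, refLabels, nNodes)
  nodeLabel <- mm$majority
  if (all(is.na(nodeLabel))) stop("all reference nodes are empty")
  coords <- gridCoordinates(m, n)
  filled <- which(!is.na(nodeLabel))
  fallback <- vapply(seq_len(nNodes), function(j) {
    if (!is.na(nodeLabel[j])) return(j)
    d2 <- (coords[filled, 1L] - coords[j, 1L])^2 +
          (coords[filled, 2L] - coords[j, 2L])^2
    filled[which.min(d2)]  # ties -> lowest filled node index
  }, integer(1))
  data.frame(label = nodeLabel[fallback[queryNodes]],
             imputed = is.na(nodeLabel[queryNodes]),
             stringsAsFactors = FALSE)
}
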