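# Quality metrics: node purity (clustering quality), matching score
# (alignment quality), per-feature grid RMSE (map agreement), and average KL
# divergence of local batch compositions (batch mixing).

.checkLabeled <- function(nodes, labels, what) {
  if (is.null(labels)) stop("labels are required for ", what)
  if (length(nodes) != length(labels))
    stop("'nodes' and 'labels' lengths differ for ", what)
  keep <- !is.na(labels)
  if (!all(keep)) {
    warning(sum(!keep), " unlabeled cell(s) excluded from ", what)
  }
  list(nodes = nodes[keep], labels = as.character(labels[keep]))
}

#' Node purity score
#'
#' For every node, each dataset's cells are compared against that dataset's
#' own per-node majority label; the score is the total number of cells
#' matching their own-dataset node mode, divided by the total number of cells
#' (both datasets). 1 means every node is pure within each dataset. This
#' measures clustering quality and is blind to whether the two maps agree.
#'
#' @param nodes1,labels1 node assignment and labels of dataset 1 cells.
#' @param nodes2,labels2 likewise for dataset 2.
#' @param nNodes total number of nodes.
#' @return A scalar in [0, 1].
#' @export
nodePurityScore <- function(nodes1, labels1, nodes2, labels2, nNodes) {
  a <- .checkLabeled(nodes1, labels1, "node purity")
  b <- .checkLabeled(nodes2, labels2, "node purity")
  m1 <- modeMap(a$nodes, a$labels, nNodes)$majority
  m2 <- modeMap(b$nodes, b$labels, nNodes)$majority
  hits <- sum(a$labels == m1[a$nodes]) + sum(b$labels == m2[b$nodes])
  hits / (length(a$nodes) + length(b$nodes))
}

#' Matching score
#'
#' For every node, dataset-1 cells are compared against the node's dataset-2
#' majority label and vice versa; the score is the number of cross-matching
#' cells divided by the total number of cells. Cells on nodes unoccupied by
#' the other dataset cannot match (the other side has no mode there) but
#' still count in the denominator. 1 means the two maps assign identically
#' labeled cells to the same nodes — the alignment is perfect.
#'
#' @inheritParams nodePurityScore
#' @return A scalar in [0, 1].
#' @export
matchingScore <- function(nodes1, labels1, nodes2, labels2, nNodes) {
  a <- .checkLabeled(nodes1, labels1, "matching score")
  b <- .checkLabeled(nodes2, labels2, "matching score")
  m1 <- modeMap(a$nodes, a$labels, nNodes)$majority
  m2 <- modeMap(b$nodes, b$labels, nNodes)$majority
  cross1 <- m2[a$nodes]  # dataset-2 mode at each dataset-1 cell's node
  cross2 <- m1[b$nodes]
  hits <- sum(a$labels == cross1, na.rm = TRUE) +
          sum(b$labels == cross2, na.rm = TRUE)
  hits / (length(a$nodes) + length(b$nodes))
}

#' Alignment RMSE over shared features of the two grids
#'
#' Root mean square difference between the two codebooks over all (node,
#' shared feature) pairs: small values mean the maps place the shared
#' features identically and are well aligned.
#'
#' @param maps a [JsomMap-class].
#' @param spec a [SharedFeatures-class] giving the column correspondence
#'   within the TRAINING feature spaces (columns of V1 / V2).
#' @return A non-negative scalar.
#' @export
alignmentRMSE <- function(maps, spec) {
  i1 <- sharedIdx1(spec); i2 <- sharedIdx2(spec)
  if (!length(i1)) stop("empty shared-feature specification")
  if (any(i1 > ncol(maps@V1)) || any(i2 > ncol(maps@V2)))
    stop("shared feature index out of range for the codebooks")
  diffs <- maps@V1[, i1, drop = FALSE] - maps@V2[, i2, drop = FALSE]
  sqrt(mean(diffs^2))
}

#' Average KL divergence of local batch compositions
#'
#' For each non-empty group (node or node cluster), the local distribution of
#' batch labels is compared with the global distribution via the
#' Kullback-Leibler divergence KL(local || global) in nats, and the
#' unweighted mean over non-empty groups is returned. 0 means every group
#' mixes the batches exactly in their global proportions; larger values mean
#' poorer mixing.
#'
#' @param groups integer vector of group (node or cluster) memberships.
#' @param batch character vector of batch labels, same length; at least two
#'   distinct batches.
#' @return A non-negative scalar (nats).
#' @export
averageKLDivergence <- function(groups, batch) {
  if (length(groups) != length(batch)) stop("'groups' and 'batch' lengths differ")
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) stop("at least two batches are required")
  g <- table(batch) / length(batch)
  labs <- names(g)
  kls <- tapply(batch, groups, function(bl) {
    p <- table(factor(bl, levels = labs)) / length(bl)
    sum(ifelse(p > 0, p * log(p / as.numeric(g)), 0))
  })
  mean(kls)
}

#' Label transfer accuracy
#'
#' Fraction of query cells whose predicted label equals the truth.
#'
#' @param predicted,truth equal-length label vectors.
#' @return A scalar in [0, 1].
#' @export
labelTransferAccuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  mean(as.character(predicted) == as.character(truth))
}
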