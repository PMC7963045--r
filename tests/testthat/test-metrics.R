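test_that("the two-node worked example scores 0.875 on purity and matching", {
  # node 1: labels1 = A,A,B and labels2 = A,A; node 2: labels1 = B, labels2 = B,B
  nodes1 <- c(1, 1, 1, 2); labels1 <- c("A", "A", "B", "B")
  nodes2 <- c(1, 1, 2, 2); labels2 <- c("A", "A", "B", "B")
  expect_equal(nodePurityScore(nodes1, labels1, nodes2, labels2, 2), 0.875)
  expect_equal(matchingScore(nodes1, labels1, nodes2, labels2, 2), 0.875)
})

test_that("purity is 1 for uniform labels and 0.5 for maximally mixed nodes", {
  n1 <- rep(1:3, each = 4); l1 <- rep("A", 12)
  expect_equal(nodePurityScore(n1, l1, n1, l1, 3), 1)
  mixed <- rep(c("A", "B"), 6)  # every node evenly split over two labels
  expect_equal(nodePurityScore(n1, mixed, n1, mixed, 3), 0.5)
})

test_that("matching score handles identical, discordant and one-sided nodes", {
  nodes <- c(1, 1, 2, 2); labels <- c("A", "A", "B", "B")
  expect_equal(matchingScore(nodes, labels, nodes, labels, 2), 1)
  # modes fully discordant across datasets at every node
  flipped <- c("B", "B", "A", "A")
  expect_equal(matchingScore(nodes, labels, nodes, flipped, 2), 0)
  # dataset 2 absent from node 2: its dataset-1 cells cannot match but count
  expect_equal(matchingScore(nodes, labels, c(1, 1), c("A", "A"), 2), 4 / 6)
})

test_that("scores are invariant under a consistent label bijection", {
  set.seed(89)
  inst <- randomMetricInstance()
  swap <- function(l) chartr("ABCD", "WXYZ", l)
  expect_equal(
    nodePurityScore(inst$nodes1, inst$labels1, inst$nodes2, inst$labels2, inst$nNodes),
    nodePurityScore(inst$nodes1, swap(inst$labels1), inst$nodes2,
                    swap(inst$labels2), inst$nNodes))
  expect_equal(
    matchingScore(inst$nodes1, inst$labels1, inst$nodes2, inst$labels2, inst$nNodes),
    matchingScore(inst$nodes1, swap(inst$labels1), inst$nodes2,
                  swap(inst$labels2), inst$nNodes))
})

test_that("alignment RMSE matches closed forms on shared codebook blocks", {
  cfg <- jsomConfig(seed = 1)
  V <- matrix(rnorm(12), 4, 3)
  maps <- new("JsomMap", m = 2L, n = 2L, V1 = V, V2 = V, config = cfg)
  sf <- sharedFeatures(1:3, 1:3)
  expect_equal(alignmentRMSE(maps, sf), 0)
  maps2 <- new("JsomMap", m = 2L, n = 2L, V1 = V, V2 = V + 1.7, config = cfg)
  expect_equal(alignmentRMSE(maps2, sf), 1.7)
  V1 <- matrix(c(1, -3), 2, 1); V2 <- matrix(0, 2, 1)
  maps3 <- new("JsomMap", m = 2L, n = 1L, V1 = V1, V2 = V2, config = cfg)
  expect_equal(alignmentRMSE(maps3, sharedFeatures(1, 1)), sqrt(5))
})

test_that("average KL divergence is 0 at perfect mixing and ln 2 at pure split", {
  groups <- rep(1:2, each = 4)
  batch <- rep(c("x", "y"), 4)  # every group mirrors the global 50/50
  expect_equal(averageKLDivergence(groups, batch), 0)
  pure <- rep(c("x", "y"), each = 4)  # each group pure in one batch
  expect_equal(averageKLDivergence(groups, pure), log(2))
  # merging two groups with identical local distributions changes nothing
  g2 <- c(1, 1, 1, 1, 2, 2, 3, 3)
  b2 <- c("x", "y", "x", "y", "x", "y", "x", "y")
  expect_equal(averageKLDivergence(g2, b2), averageKLDivergence(rep(1, 8), b2))
  expect_error(averageKLDivergence(groups, rep("x", 8)), "two batches")
})

test_that("label transfer accuracy counts exact agreements", {
  expect_equal(labelTransferAccuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(labelTransferAccuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(labelTransferAccuracy(rep("a", 8), c(rep("a", 7), "b")), 0.875)
  expect_error(labelTransferAccuracy("a", c("a", "b")), "mismatch")
})

test_that("metrics agree with brute-force recomputation on random instances", {
  set.seed(97)
  for (i in 1:40) {
    inst <- randomMetricInstance()
    expect_equal(
      nodePurityScore(inst$nodes1, inst$labels1, inst$nodes2, inst$labels2,
                      inst$nNodes),
      brutePurity(inst$nodes1, inst$labels1, inst$nodes2, inst$labels2,
                  inst$nNodes),
      tolerance = 1e-12)
    expect_equal(
      matchingScore(inst$nodes1, inst$labels1, inst$nodes2, inst$labels2,
                    inst$nNodes),
      bruteMatching(inst$nodes1, inst$labels1, inst$nodes2, inst$labels2,
                    inst$nNodes),
      tolerance = 1e-12)
    batch <- sample(c("b1", "b2"), inst$nNodes * 3, replace = TRUE)
    groups <- sample(inst$nNodes, inst$nNodes * 3, replace = TRUE)
    expect_equal(averageKLDivergence(groups, batch), bruteAvgKL(groups, batch),
                 tolerance = 1e-12)
  }
})

test_that("unlabeled cells are excluded with a warning", {
  nodes <- c(1, 1, 2, 2); labels <- c("A", NA, "B", "B")
  full <- c("A", "A", "B", "B")
  expect_warning(s <- nodePurityScore(nodes, labels, nodes, full, 2),
                 "unlabeled")
  expect_equal(s, 1)
})
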