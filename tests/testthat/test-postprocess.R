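makeToyMap <- function(V1, V2, m, n) {
  new("JsomMap", m = as.integer(m), n = as.integer(n), V1 = V1, V2 = V2,
      config = jsomConfig(m = max(2, m), n = max(2, n), seed = 1))
}

test_that("cells land on their nearest nodes, matching a brute-force scan", {
  set.seed(67)
  V1 <- matrix(rnorm(16), 4, 4); V2 <- matrix(rnorm(12), 4, 3)
  maps <- makeToyMap(V1, V2, 2, 2)
  d1 <- jsomDataset(V1[c(3, 1, 4, 2), ])  # exact codebook copies
  d2 <- jsomDataset(matrix(rnorm(12), 4, 3))
  asg <- assignToNodes(d1, d2, maps)
  expect_equal(nodes1(asg), c(3L, 1L, 4L, 2L))
  expect_equal(nodes2(asg),
               vapply(1:4, function(i) bruteBMU(values(d2)[i, ], V2), integer(1)))
  expect_error(assignToNodes(jsomDataset(matrix(1, 2, 7)), d2, maps),
               "dimension")
})

test_that("assignment is permutation-equivariant over cells", {
  set.seed(71)
  maps <- makeToyMap(matrix(rnorm(18), 6, 3), matrix(rnorm(18), 6, 3), 2, 3)
  X <- matrix(rnorm(30), 10, 3)
  perm <- sample(10)
  a <- assignToNodes(jsomDataset(X), jsomDataset(X), maps)
  b <- assignToNodes(jsomDataset(X[perm, ]), jsomDataset(X), maps)
  expect_equal(nodes1(b), nodes1(a)[perm])
})

test_that("mode maps report per-node majorities with deterministic ties", {
  mm <- modeMap(c(1, 1, 1, 3, 3), c("A", "A", "B", "A", "B"), 4)
  expect_equal(mm$majority, c("A", NA, "A", NA))  # node 3 ties A/B -> A
  expect_equal(mm$counts[1, ], c(A = 2L, B = 1L))
  expect_equal(sum(mm$counts), 5L)
})

test_that("superposition clustering cuts the Ward tree at K groups", {
  set.seed(73)
  # 12 nodes in 3 well-separated codebook blobs
  blob <- rep(1:3, each = 4)
  V1 <- matrix(rnorm(24, sd = 0.1), 12, 2) + cbind(blob * 30, -blob * 30)
  V2 <- matrix(rnorm(24, sd = 0.1), 12, 2) + cbind(blob * 10, blob * 50)
  maps <- makeToyMap(V1, V2, 3, 4)
  cl <- superposeCluster(maps, K = 3)
  expect_equal(attr(cl, "K"), 3L)
  expect_equal(as.integer(cl), blob)  # first-occurrence relabeling
  expect_equal(as.integer(superposeCluster(maps, K = 1)), rep(1L, 12))
  expect_equal(as.integer(superposeCluster(maps, K = 12)), 1:12)
  expect_error(superposeCluster(maps, K = 13), "between")
})

test_that("superposition clustering is invariant to node reordering up to labels", {
  set.seed(79)
  V1 <- matrix(rnorm(20), 10, 2); V2 <- matrix(rnorm(20), 10, 2)
  maps <- makeToyMap(V1, V2, 2, 5)
  perm <- sample(10)
  mapsP <- makeToyMap(V1[perm, ], V2[perm, ], 2, 5)
  cl <- as.integer(superposeCluster(maps, K = 4))
  clP <- as.integer(superposeCluster(mapsP, K = 4))
  # same partition of nodes, possibly different labels
  for (a in 1:10) for (b in 1:10) {
    expect_equal(cl[a] == cl[b], clP[match(a, perm)] == clP[match(b, perm)])
  }
})

test_that("composition tables give per-label percentages summing to 100", {
  asg <- new("JsomAssignment", nodes1 = c(1L, 1L, 2L, 2L, 3L),
             nodes2 = c(1L, 3L, 3L), nNodes = 4L)
  cl <- structure(c(1L, 1L, 2L, 2L), K = 2L)
  labels1 <- c("T", "T", "B", "B", "B")
  labels2 <- c("T", "B", "B")
  tabs <- compositionTable(asg, cl, labels1, labels2)
  expect_equal(unname(colSums(tabs$dataset1)), c(100, 100))
  expect_equal(tabs$dataset1["1", "T"], 100)  # all T cells in cluster 1
  expect_equal(tabs$dataset1["1", "B"], 200 / 3)  # 2 of 3 B cells in cluster 1
  expect_equal(tabs$dataset2["2", "B"], 100)
  expect_error(compositionTable(asg, cl), "labels")
})

test_that("label transfer uses node majorities with nearest-node imputation", {
  # 2x2 grid; reference occupies nodes 1 and 4 only
  pred <- transferLabels(refNodes = c(1, 1, 4), refLabels = c("B", "B", "T"),
                         queryNodes = c(1, 4, 2), m = 2, n = 2)
  expect_equal(pred$label[1:2], c("B", "T"))
  expect_false(any(pred$imputed[1:2]))
  # node 2 at (0,1) is equidistant from nodes 1 and 4: lowest index wins
  expect_equal(pred$label[3], "B")
  expect_true(pred$imputed[3])
  expect_error(transferLabels(integer(0), character(0), 1L, 2, 2), "empty")
})

test_that("transfer onto the reference itself reproduces its node purity", {
  set.seed(83)
  nodes <- sample(9, 60, replace = TRUE)
  labels <- sample(c("B", "T", "NK"), 60, replace = TRUE)
  pred <- transferLabels(nodes, labels, nodes, 3, 3)
  acc <- labelTransferAccuracy(pred$label, labels)
  pur <- nodePurityScore(nodes, labels, nodes, labels, 9)
  expect_equal(acc, pur)
  # never invents a label absent from the reference
  expect_true(all(pred$label %in% labels))
})
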