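test_that("the schedule interpolates linearly between its endpoints", {
  cfg <- jsomConfig(alpha0 = 0.9, alphaFinal = 0.01, epsilon0 = 6, seed = 1)
  expect_equal(schedule(cfg, 0, 100), c(alpha = 0.9, epsilon = 6))
  expect_equal(schedule(cfg, 99, 100), c(alpha = 0.01, epsilon = 0))
  mid <- schedule(cfg, 49.5, 100)
  expect_equal(mid[["alpha"]], (0.9 + 0.01) / 2)
  expect_equal(mid[["epsilon"]], 3)
  # degenerate run lengths keep the initial values
  expect_equal(schedule(cfg, 0, 1), c(alpha = 0.9, epsilon = 6))
})

test_that("default neighborhood radius covers a third of the grid diameter", {
  expect_equal(defaultEpsilon0(10, 10), 6)
  expect_equal(defaultEpsilon0(2, 2), 1)
  expect_equal(defaultEpsilon0(15, 15), ceiling(28 / 3))
  expect_equal(defaultEpsilon0(10, 10, literal = TRUE), 7)
  expect_equal(defaultEpsilon0(3, 3, literal = TRUE), 0)
})

test_that("codebook updates follow V + delta*alpha*(x - V) exactly", {
  V <- rbind(c(0, 0), c(4, 4), c(8, 8))
  expect_identical(applyUpdate(V, 1:3, c(1, 1), 0, 0.9), V)
  full <- applyUpdate(V, c(1, 3), c(2, 4), 1, 1)
  expect_equal(full[1, ], c(2, 4))
  expect_equal(full[3, ], c(2, 4))
  expect_equal(full[2, ], c(4, 4))  # untouched
  got <- applyUpdate(rbind(c(0, 0)), 1, c(2, 4), 0.5, 0.9)
  expect_equal(got[1, ], c(0.9, 1.8))
  expect_error(applyUpdate(V, 1, c(1, 2, 3), 1, 0.5), "mismatch")
})

test_that("map initialization is seeded and stays inside the data ranges", {
  set.seed(43)
  d1 <- jsomDataset(matrix(rnorm(30 * 14), 30, 14))
  d2 <- jsomDataset(matrix(runif(30 * 5, -2, 9), 30, 5))
  cfg <- jsomConfig(seed = 43)
  m1 <- initializeMaps(cfg, d1, d2)
  m2 <- initializeMaps(cfg, d1, d2)
  expect_identical(codebook1(m1), codebook1(m2))
  expect_identical(codebook2(m1), codebook2(m2))
  expect_equal(dim(codebook1(m1)), c(100L, 14L))
  for (j in 1:14) {
    expect_true(all(codebook1(m1)[, j] >= min(values(d1)[, j])))
    expect_true(all(codebook1(m1)[, j] <= max(values(d1)[, j])))
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(47)
  sim <- generatePaired(simSpec(kClusters = 3, cellsPerCluster = 30, seed = 4))
  m <- buildMatching(sim$d1, sim$d2, sim$shared)
  cfg <- jsomConfig(m = 4, n = 4, epochs = 2, seed = 9)
  a <- trainJsom(sim$d1, sim$d2, m, cfg)
  b <- trainJsom(sim$d1, sim$d2, m, cfg)
  expect_identical(codebook1(a), codebook1(b))
  expect_identical(codebook2(a), codebook2(b))
})

test_that("joint coupling drives duplicate datasets onto near-identical maps", {
  # with d1 == d2 and identity matching the two maps receive the same update
  # targets (their draws and initializations differ); the coupling must pull
  # the codebooks together far below the data scale, while uncoupled maps of
  # the same data stay apart
  set.seed(53)
  sim <- generatePaired(simSpec(kClusters = 3, cellsPerCluster = 80,
                                sharedDistortion = 0, seed = 5))
  d <- sim$d1
  sf <- sharedFeatures(seq_len(nFeatures(d)), seq_len(nFeatures(d)))
  cfg <- jsomConfig(m = 5, n = 5, epochs = 3, seed = 5)
  coupled <- trainJsom(d, d, identityMatching(nCells(d)), cfg)
  uncoupled <- trainJsom(d, d, identityMatching(nCells(d)),
                         jsomConfig(m = 5, n = 5, epochs = 3, seed = 5,
                                    joint = FALSE))
  expect_lt(alignmentRMSE(coupled, sf), alignmentRMSE(uncoupled, sf) / 3)
  expect_lt(alignmentRMSE(coupled, sf), 0.25 * sd(values(d)))
})

test_that("codebook components never leave the data/init convex hull", {
  set.seed(59)
  sim <- generatePaired(simSpec(kClusters = 3, cellsPerCluster = 40, seed = 6))
  m <- buildMatching(sim$d1, sim$d2, sim$shared)
  cfg <- jsomConfig(m = 5, n = 5, epochs = 2, seed = 6)
  maps <- trainJsom(sim$d1, sim$d2, m, cfg)
  for (j in seq_len(nFeatures(sim$d1))) {
    lo <- min(values(sim$d1)[, j]); hi <- max(values(sim$d1)[, j])
    expect_true(all(codebook1(maps)[, j] >= lo - 1e-9))
    expect_true(all(codebook1(maps)[, j] <= hi + 1e-9))
  }
})

test_that("training reduces the quantization error from initialization", {
  set.seed(61)
  sim <- generatePaired(simSpec(kClusters = 4, cellsPerCluster = 60, seed = 8))
  m <- buildMatching(sim$d1, sim$d2, sim$shared)
  cfg <- jsomConfig(seed = 8)
  init <- initializeMaps(cfg, sim$d1, sim$d2)
  trained <- trainJsom(sim$d1, sim$d2, m, cfg)
  qe0 <- quantizationError(values(sim$d1), codebook1(init))
  qe1 <- quantizationError(values(sim$d1), codebook1(trained))
  expect_lt(qe1, qe0)
})

test_that("matching size mismatches are rejected", {
  d <- jsomDataset(matrix(rnorm(40), 10, 4))
  cfg <- jsomConfig(m = 3, n = 3, seed = 1)
  expect_error(trainJsom(d, d, identityMatching(9), cfg), "matching size")
})
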