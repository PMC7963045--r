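test_that("pearson matching recovers exact self-matches with delta 1", {
  set.seed(1)
  A <- matrix(rnorm(60), 12, 5)
  m <- pearsonMatch(A, A)
  expect_equal(matchIndices(m, "1to2"), 1:12)
  expect_equal(matchIndices(m, "2to1"), 1:12)
  expect_equal(matchWeights(m, 1), rep(1, 12), tolerance = 1e-12)
  expect_identical(matchingMode(m), "correlation")
})

test_that("pearson matching prefers positive linear relations and clamps negatives", {
  A <- rbind(c(1, 2, 3))
  B <- rbind(c(2, 4, 6), c(3, 2, 1))
  m <- pearsonMatch(A, B)
  expect_equal(matchIndices(m, "1to2"), 1L)
  expect_equal(matchWeights(m, 1), 1, tolerance = 1e-12)
  # only candidate is perfectly anti-correlated: clamped to 0 by default
  onlyNeg <- pearsonMatch(rbind(c(3, 2, 1)), rbind(c(1, 2, 3)))
  expect_equal(matchWeights(onlyNeg, 1), 0)
  raw <- pearsonMatch(rbind(c(3, 2, 1)), rbind(c(1, 2, 3)), allowNegative = TRUE)
  expect_equal(matchWeights(raw, 1), -1, tolerance = 1e-12)
})

test_that("constant rows get delta 0, lowest-index match, and a warning", {
  A <- rbind(c(5, 5, 5), c(1, 2, 3))
  B <- rbind(c(1, 3, 2), c(0, 1, 2))
  expect_warning(m <- pearsonMatch(A, B), "constant")
  expect_equal(matchIndices(m, "1to2")[1], 1L)
  expect_equal(matchWeights(m, 1)[1], 0)
})

test_that("pearson matching is invariant to positive affine rescaling of rows", {
  set.seed(3)
  A <- matrix(rnorm(40), 8, 5)
  B <- matrix(rnorm(50), 10, 5)
  base <- pearsonMatch(A, B)
  A2 <- A
  for (i in seq_len(nrow(A2))) A2[i, ] <- runif(1, 0.5, 3) * A2[i, ] + rnorm(1)
  scaled <- pearsonMatch(A2, B)
  expect_equal(matchIndices(scaled, "1to2"), matchIndices(base, "1to2"))
  expect_equal(matchWeights(scaled, 1), matchWeights(base, 1), tolerance = 1e-9)
})

test_that("step threshold matches hand-computable cases and rejects flat input", {
  r <- stepminerThreshold(c(1, 1, 1, 5, 5, 5))
  expect_equal(r$threshold, 3.0)
  expect_equal(r$splitIndex, 3L)
  r2 <- stepminerThreshold(c(0, 0, 1, 10))
  b2 <- bruteStepminer(c(0, 0, 1, 10))
  expect_equal(r2$threshold, b2$threshold)
  expect_equal(r2$splitIndex, b2$splitIndex)
  expect_error(stepminerThreshold(c(2, 2, 2, 2)), "degenerate")
  expect_error(stepminerThreshold(3), "at least 2")
})

test_that("step threshold equals exhaustive SSE minimization on random vectors", {
  set.seed(11)
  for (i in 1:60) {
    len <- sample(2:80, 1)
    x <- round(rnorm(len, sd = sample(1:5, 1)), 2)
    if (max(x) == min(x)) next
    got <- stepminerThreshold(x)
    want <- bruteStepminer(x)
    expect_equal(got$splitIndex, want$splitIndex)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("binarization thresholds each column and drops constant ones", {
  bv <- binarizeDataset(cbind(c(1, 1, 5, 5), c(0, 2, 8, 10)))
  expect_equal(bv$bits[, 1], c(0L, 0L, 1L, 1L))
  expect_equal(bv$thresholds[1], 3.0)
  expect_warning(bv2 <- binarizeDataset(cbind(c(1, 1, 5, 5), c(7, 7, 7, 7))),
                 "constant")
  expect_equal(bv2$kept, 1L)
  expect_equal(ncol(bv2$bits), 1L)
})

test_that("binary matching counts agreeing features", {
  bin <- function(m) list(bits = m)
  A <- rbind(c(1, 0, 1, 0))
  B <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 1))
  m <- binaryMatch(bin(A), bin(B))
  expect_equal(matchIndices(m, "1to2"), 1L)
  expect_equal(matchWeights(m, 1), 0.75)
  comp <- binaryMatch(bin(rbind(c(1, 0, 1))), bin(rbind(c(0, 1, 0))))
  expect_equal(matchWeights(comp, 1), 0)
  ident <- binaryMatch(bin(A), bin(A))
  expect_equal(matchWeights(ident, 1), 1)
  expect_error(binaryMatch(bin(A), bin(rbind(c(1, 0)))), "same number")
})

test_that("binary similarity is symmetric so mutual best matches share delta", {
  set.seed(21)
  A <- matrix(rbinom(40, 1, 0.5), 8, 5)
  B <- matrix(rbinom(35, 1, 0.5), 7, 5)
  m <- binaryMatch(list(bits = A), list(bits = B))
  for (a in seq_len(8)) {
    b <- matchIndices(m, "1to2")[a]
    if (matchIndices(m, "2to1")[b] == a)
      expect_equal(matchWeights(m, 1)[a], matchWeights(m, 2)[b])
  }
})

test_that("buildMatching extracts shared columns and dispatches by mode", {
  set.seed(5)
  X <- matrix(rnorm(48), 8, 6)
  d <- jsomDataset(X)
  sf <- sharedFeatures(1:4, 1:4)
  m <- buildMatching(d, d, sf, mode = "correlation")
  expect_equal(matchIndices(m, "1to2"), 1:8)
  expect_equal(matchWeights(m, 1), rep(1, 8), tolerance = 1e-12)

  # matching must depend only on the shared columns
  X2 <- X
  X2[, 5:6] <- matrix(rnorm(16, sd = 50), 8, 2)
  m2 <- buildMatching(jsomDataset(X2), d, sf, mode = "correlation")
  expect_equal(matchIndices(m2, "1to2"), matchIndices(m, "1to2"))

  # binary mode equals the binarize + binary-match composition
  Yb <- matrix(sample(c(0, 1, 5, 6), 60, replace = TRUE), 10, 6)
  db <- jsomDataset(Yb)
  mb <- buildMatching(db, db, sf, mode = "binary")
  direct <- binaryMatch(binarizeDataset(Yb[, 1:4]), binarizeDataset(Yb[, 1:4]))
  expect_equal(matchIndices(mb, "1to2"), matchIndices(direct, "1to2"))
  expect_equal(matchWeights(mb, 1), matchWeights(direct, 1))
})

test_that("binary mode drops a shared pair constant in either dataset", {
  A <- cbind(c(1, 1, 9, 9), c(4, 4, 4, 4), c(0, 1, 7, 8))
  B <- cbind(c(2, 2, 8, 8), c(1, 2, 8, 9), c(0, 1, 7, 8))
  dA <- jsomDataset(A); dB <- jsomDataset(B)
  sf <- sharedFeatures(1:3, 1:3)
  expect_warning(m <- buildMatching(dA, dB, sf, mode = "binary"), "dropped")
  ref <- binaryMatch(binarizeDataset(A[, c(1, 3)]), binarizeDataset(B[, c(1, 3)]))
  expect_equal(matchWeights(m, 1), matchWeights(ref, 1))
})

test_that("all matching weights stay within [0, 1] by default", {
  set.seed(31)
  for (i in 1:10) {
    A <- matrix(rnorm(sample(5:15, 1) * 4), ncol = 4)
    B <- matrix(rnorm(sample(5:15, 1) * 4), ncol = 4)
    m <- pearsonMatch(A, B)
    expect_true(all(matchWeights(m, 1) >= 0 & matchWeights(m, 1) <= 1))
    expect_true(all(matchWeights(m, 2) >= 0 & matchWeights(m, 2) <= 1))
  }
})
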