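# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, without calling the package's
# computation paths.

bruteBMU <- function(x, V) {
  which.min(apply(V, 1L, function(v) sum((x - v)^2)))
}

# Exhaustive SSE minimization over all two-segment splits of sorted values.
bruteStepminer <- function(x) {
  xs <- sort(x)
  len <- length(xs)
  sse <- vapply(seq_len(len - 1L), function(s) {
    left <- xs[seq_len(s)]; right <- xs[(s + 1L):len]
    sum((left - mean(left))^2) + sum((right - mean(right))^2)
  }, numeric(1))
  s <- which.min(sse)
  list(threshold = (mean(xs[seq_len(s)]) + mean(xs[(s + 1L):len])) / 2,
       splitIndex = s)
}

bruteMode <- function(labels) {
  if (!length(labels)) return(NA_character_)
  counts <- table(labels)
  sorted <- sort(names(counts)[counts == max(counts)])
  sorted[1L]
}

brutePurity <- function(nodes1, labels1, nodes2, labels2, nNodes) {
  hits <- 0L
  for (j in seq_len(nNodes)) {
    l1 <- labels1[nodes1 == j]; l2 <- labels2[nodes2 == j]
    if (length(l1)) hits <- hits + sum(l1 == bruteMode(l1))
    if (length(l2)) hits <- hits + sum(l2 == bruteMode(l2))
  }
  hits / (length(labels1) + length(labels2))
}

bruteMatching <- function(nodes1, labels1, nodes2, labels2, nNodes) {
  hits <- 0L
  for (j in seq_len(nNodes)) {
    l1 <- labels1[nodes1 == j]; l2 <- labels2[nodes2 == j]
    m1 <- bruteMode(l1); m2 <- bruteMode(l2)
    if (length(l1) && !is.na(m2)) hits <- hits + sum(l1 == m2)
    if (length(l2) && !is.na(m1)) hits <- hits + sum(l2 == m1)
  }
  hits / (length(labels1) + length(labels2))
}

bruteRMSE <- function(V1, V2, idx1, idx2) {
  total <- 0; nterms <- 0L
  for (j in seq_len(nrow(V1))) {
    for (k in seq_along(idx1)) {
      total <- total + (V1[j, idx1[k]] - V2[j, idx2[k]])^2
      nterms <- nterms + 1L
    }
  }
  sqrt(total / nterms)
}

bruteAvgKL <- function(groups, batch) {
  labs <- sort(unique(batch))
  g <- vapply(labs, function(b) mean(batch == b), numeric(1))
  kls <- vapply(sort(unique(groups)), function(grp) {
    bl <- batch[groups == grp]
    p <- vapply(labs, function(b) mean(bl == b), numeric(1))
    sum(p[p > 0] * log(p[p > 0] / g[p > 0]))
  }, numeric(1))
  mean(kls)
}

# A classical (single-map) SOM written from the textbook definition,
# replicating the package's documented randomness protocol (seed -> init V1
# then V2 column by column -> per-epoch permutations for dataset 1 then 2) so
# draws coincide, while recomputing BMUs, neighborhoods, schedules and
# updates itself.
plainSOM <- function(X1, X2, cfg) {
  k <- cfg@m * cfg@n
  set.seed(cfg@seed)
  initV <- function(X) {
    V <- matrix(0, k, ncol(X))
    for (j in seq_len(ncol(X))) V[, j] <- runif(k, min(X[, j]), max(X[, j]))
    V
  }
  V1 <- initV(X1); V2 <- initV(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  total <- cfg@epochs * max(n1, n2)
  drawSeq <- function(n) {
    idx <- unlist(lapply(seq_len(ceiling(total / n)), function(e) sample.int(n)))
    idx[seq_len(total)]
  }
  seq1 <- drawSeq(n1); seq2 <- drawSeq(n2)
  coords <- cbind((seq_len(k) - 1L) %/% cfg@n, (seq_len(k) - 1L) %% cfg@n)
  for (t in seq_len(total)) {
    frac <- (t - 1) / (total - 1)
    if (frac >= 1) {
      a <- cfg@alphaFinal; eps <- 0
    } else {
      a <- max(cfg@alphaFinal, cfg@alpha0 + (cfg@alphaFinal - cfg@alpha0) * frac)
      eps <- max(0, cfg@epsilon0 * (1 - frac))
    }
    for (side in 1:2) {
      X <- if (side == 1) X1 else X2
      V <- if (side == 1) V1 else V2
      x <- X[(if (side == 1) seq1 else seq2)[t], ]
      b <- which.min(apply(V, 1L, function(v) sum((x - v)^2)))
      d2 <- (coords[, 1L] - coords[b, 1L])^2 + (coords[, 2L] - coords[b, 2L])^2
      nb <- which(d2 <= eps^2)
      for (j in nb) V[j, ] <- V[j, ] + 1 * a * (x - V[j, ])
      if (side == 1) V1 <- V else V2 <- V
    }
  }
  list(V1 = V1, V2 = V2)
}

# Identity matching with unit weights over n cells (both datasets same size).
identityMatching <- function(n, mode = "correlation") {
  new("JsomMatching", match1to2 = seq_len(n), match2to1 = seq_len(n),
      delta1 = rep(1, n), delta2 = rep(1, n), mode = mode)
}

# Random labeled toy assignment instance for metric oracle sweeps.
randomMetricInstance <- function(maxCells = 100, maxNodes = 9) {
  nNodes <- sample(2:maxNodes, 1)
  n1 <- sample(1:maxCells, 1); n2 <- sample(1:maxCells, 1)
  labs <- LETTERS[1:sample(2:4, 1)]
  list(nodes1 = sample(nNodes, n1, replace = TRUE),
       labels1 = sample(labs, n1, replace = TRUE),
       nodes2 = sample(nNodes, n2, replace = TRUE),
       labels2 = sample(labs, n2, replace = TRUE),
       nNodes = nNodes)
}
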