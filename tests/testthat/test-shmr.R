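test_that("Pearson network handles perfect correlation and degenerate input", {
  t1 <- rnorm(50)
  ts <- cbind(a = t1, b = t1, c = -t1, d = rnorm(50))
  P <- pearsonNetwork(ts)
  expect_equal(P["a", "b"], 1)
  expect_equal(P["a", "c"], -1)
  expect_equal(diag(P), setNames(rep(1, 4), colnames(ts)))
  expect_true(all(abs(P) <= 1 + 1e-12))

  tsBad <- cbind(x = rnorm(10), flat = rep(2, 10))
  expect_error(pearsonNetwork(tsBad), "flat")
})

test_that("Pearson estimates recover the modular covariance", {
  M <- makeModularCovariance(4, 2, withinCorr = 0.6, betweenCorr = 0.1)
  X <- generateTimeSeries(M, 200, seed = 11)
  P <- pearsonNetwork(X)
  expect_lt(max(abs(c(P[1, 2], P[3, 4]) - 0.6)), 0.15)
})

test_that("kNN hyperedges pick the most correlated neighbors", {
  corr <- matrix(c(1, 0.9, 0.1,
                   0.9, 1, 0.2,
                   0.1, 0.2, 1), 3, 3)
  hg <- buildHypergraph(corr, knnK = 1L)
  H <- incidenceMatrix(hg)
  expect_equal(H[, 1], c(1, 1, 0))  # edge 1 = {1,2}
  expect_equal(H[, 2], c(1, 1, 0))  # edge 2 = {2,1}
  expect_equal(H[, 3], c(0, 1, 1))  # edge 3 = {3,2}
  expect_equal(edgeWeights(hg), c(0.9, 0.9, 0.2))

  # zero off-diagonal: ties resolved by lowest index
  hg0 <- buildHypergraph(diag(3), knnK = 1L)
  H0 <- incidenceMatrix(hg0)
  expect_equal(H0[, 1], c(1, 1, 0))
  expect_equal(H0[, 3], c(1, 0, 1))

  set.seed(1)
  C <- cov2cor(crossprod(matrix(rnorm(200), 20, 10)))
  hgR <- buildHypergraph(C, knnK = 4L)
  expect_true(all(edgeDegrees(hgR) == 5))
  expect_error(buildHypergraph(C, knnK = 0L), "positive")
  expect_error(buildHypergraph(C, knnK = 10L), "smaller")
})

test_that("hypergraph Laplacian matches the closed form for one big edge", {
  N <- 6
  hg <- new("Hypergraph", incidence = matrix(1, N, 1), edgeWeights = 1)
  L <- hypergraphLaplacian(hg)
  expect_equal(L, diag(N) - matrix(1 / N, N, N))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, rep(1, N - 1)))
})

test_that("Laplacian is PSD with the degree-scaled null vector", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    C <- cov2cor(crossprod(matrix(rnorm(3 * n * n), 3 * n, n)))
    hg <- buildHypergraph(C, knnK = sample(2:4, 1))
    L <- hypergraphLaplacian(hg)
    expect_lt(max(abs(L - t(L))), 1e-12)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    v <- sqrt(vertexDegrees(hg))
    expect_lt(max(abs(L %*% v)), 1e-10)
  }
})

test_that("soft threshold matches its closed form", {
  x <- c(-3, -0.5, 0, 0.2, 4)
  expect_equal(hlrnet:::.softThreshold(x, 1),
               sign(x) * pmax(abs(x) - 1, 0))
})

test_that("unregularized SHMR returns the Pearson matrix", {
  set.seed(3)
  X <- generateTimeSeries(makeModularCovariance(6, 2, 0.5, 0.1), 80, seed = 3)
  P <- fitSHMR(X, params = shmrParams(lambda = 0, gamma = 0))
  C <- pearsonNetwork(X)
  off <- upper.tri(C)
  expect_lt(max(abs(P[off] - C[off])), 1e-8)
  expect_equal(diag(P), setNames(rep(0, 6), colnames(C)))
})

test_that("SHMR objective is monotone and dominates the unpenalized start", {
  set.seed(4)
  X <- generateTimeSeries(makeModularCovariance(8, 2, 0.5, 0.1), 60, seed = 4)
  C <- pearsonNetwork(X)
  L <- hypergraphLaplacian(buildHypergraph(C, 3L))
  P <- fitSHMR(X, L, shmrParams())
  trace <- attr(P, "objective")
  expect_true(all(diff(trace) <= 1e-10))
  expect_lte(trace[length(trace)],
             shmrObjective(C, C, L, 2^-3, 2^-4))
})

test_that("sparsity weight sweep produces non-increasing density", {
  set.seed(5)
  X <- generateTimeSeries(makeModularCovariance(8, 2, 0.5, 0.1), 60, seed = 5)
  C <- pearsonNetwork(X)
  L <- hypergraphLaplacian(buildHypergraph(C, 3L))
  nnz <- vapply(c(0, 0.05, 0.1, 0.25, 0.5, 1), function(g) {
    P <- fitSHMR(X, L, shmrParams(gamma = g))
    sum(abs(P) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("SHMR solution matches an independent coordinate-descent oracle", {
  set.seed(6)
  X <- generateTimeSeries(makeModularCovariance(5, 2, 0.5, 0.1), 40, seed = 6)
  C <- pearsonNetwork(X)
  L <- hypergraphLaplacian(buildHypergraph(C, 2L))
  lambda <- 2^-3; gamma <- 2^-4
  P <- suppressWarnings(
    fitSHMR(X, L, shmrParams(lambda = lambda, gamma = gamma, tol = 1e-11,
                             maxIter = 5000L)))
  objFit <- tail(attr(P, "objective"), 1)
  # oracle: cyclic exact coordinate minimization (closed-form scalar prox
  # per entry given all others), an independent route to the same convex
  # optimum
  Po <- C
  for (sweep in 1:500) {
    changed <- 0
    for (i in 1:5) for (j in 1:5) {
      # in entry p = P[i,j] the objective is
      # (1 + lambda L_ii) p^2 - 2 (C_ij - lambda rest) p + gamma |p| + const
      rest <- sum(L[i, ] * Po[, j]) - L[i, i] * Po[i, j]
      a <- 1 + lambda * L[i, i]
      pHat <- (C[i, j] - lambda * rest) / a
      thr <- gamma / (2 * a)
      pNew <- sign(pHat) * max(abs(pHat) - thr, 0)
      changed <- max(changed, abs(pNew - Po[i, j]))
      Po[i, j] <- pNew
    }
    if (changed < 1e-12) break
  }
  objOracle <- shmrObjective(Po, C, L, lambda, gamma)
  expect_lt(abs(objFit - objOracle), 1e-4)
})

test_that("non-convergence raises a warning and flags the iterate", {
  set.seed(7)
  X <- generateTimeSeries(diag(5), 30, seed = 7)
  expect_warning(P <- fitSHMR(X, params = shmrParams(maxIter = 1L)),
                 "did not converge")
  expect_false(attr(P, "converged"))
})
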