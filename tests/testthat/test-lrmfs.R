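test_that("K-sparse simplex weights satisfy the closed form", {
  # only one candidate: all mass on it
  expect_equal(simplexNeighborWeights(c(0.7), 1), 1)
  # nearer of two candidates takes all mass at K = 1
  expect_equal(simplexNeighborWeights(c(0, 2), 1), c(1, 0))
  # equal distances: uniform over the K nearest
  expect_equal(simplexNeighborWeights(rep(3, 4), 2), c(0.5, 0.5, 0, 0))
  # generic: exactly K nonzeros summing to one
  set.seed(11)
  for (i in 1:50) {
    m <- sample(4:12, 1); K <- sample(1:3, 1)
    d <- runif(m)
    s <- simplexNeighborWeights(d, K)
    expect_equal(sum(s), 1)
    expect_lte(sum(s > 0), K)
    expect_true(all(s >= 0))
    # oracle: simplex projection of -d/(2 alpha) with the K-neighbor alpha
    a <- kNeighborAlpha(d, K)
    if (a > 1e-12) {
      so <- simplexQpOracle(d, a)
      fOracle <- sum(d * so) + a * sum(so^2)
      fPkg <- sum(d * s) + a * sum(s^2)
      expect_lt(abs(fPkg - fOracle), 1e-6)
    }
  }
})

test_that("initial similarity is label-respecting and matches the QP oracle", {
  set.seed(12)
  fs <- makeTinyFeatureSet(n = 10, d = 6, seed = 12)
  y <- classLabels(fs)
  S <- initSimilarity(fs, K = 2)
  expect_equal(unname(rowSums(S)), rep(1, 10))
  expect_true(all(S[outer(y, y, "!=")] == 0))
  expect_equal(diag(S), rep(0, 10))

  X <- featureMatrices(fs)
  for (i in 1:10) {
    cand <- setdiff(which(y == y[i]), i)
    d <- colSums((X[[1]][, cand] - X[[1]][, i])^2) +
      colSums((X[[2]][, cand] - X[[2]][, i])^2)
    a <- kNeighborAlpha(d, 2)
    so <- simplexQpOracle(d, a)
    expect_lt(max(abs(S[i, cand] - so)), 1e-6)
  }

  # two same-class samples, K = 1: all mass on the only neighbor
  fs2 <- multimodalFeatureSet(list(matrix(rnorm(8), 2, 4)), c(1, 1, -1, -1))
  S2 <- initSimilarity(fs2, K = 1)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[2, 1], 1)
  expect_equal(S2[1, 3], 0)
  expect_error(initSimilarity(fs2, K = 2), "more than K")
})

test_that("column l2,1 prox shrinks norms by the closed form", {
  expect_equal(l21Prox(matrix(c(3, 4)), 1), matrix(c(2.4, 3.2)))
  expect_equal(l21Prox(matrix(c(0.3, 0.4)), 1), matrix(c(0, 0)))
  set.seed(13)
  for (i in 1:1000) {
    p <- rnorm(sample(2:5, 1), sd = 2)
    t <- runif(1, 0, 3)
    e <- drop(l21Prox(matrix(p), t))
    # 1-D oracle on the norm of the solution
    nrm <- sqrt(sum(p^2))
    f <- function(s) t * s + 0.5 * (s - nrm)^2
    sStar <- optimize(f, c(0, nrm + 1), tol = 1e-10)$minimum
    fOracle <- min(f(sStar), f(0))  # boundary candidate included
    fPkg <- t * sqrt(sum(e^2)) + 0.5 * sum((e - p)^2)
    expect_lt(abs(fPkg - fOracle), 1e-6)
  }
})

test_that("Procrustes update is optimal over orthonormal matrices", {
  set.seed(14)
  Q0 <- randomOrthonormal(5, 2)
  expect_equal(orthProcrustes(Q0), Q0)

  Q <- matrix(rnorm(12), 6, 2)
  V <- orthProcrustes(Q)
  expect_lt(max(abs(crossprod(V) - diag(2))), 1e-10)
  best <- sum(V * Q)
  for (i in 1:200) {
    cand <- randomOrthonormal(6, 2)
    expect_lte(sum(cand * Q), best + 1e-10)
  }
})

test_that("weight subsystem solves its normal equations exactly", {
  set.seed(15)
  d <- 8; n <- 20
  X <- matrix(rnorm(d * n), d, n)
  y <- rep(c(1, -1), 10)
  # unregularized square case: plain least squares
  w0 <- hlrnet:::.solveW(tcrossprod(X), matrix(0, d, d), drop(X %*% y),
                         rep(1, d), 0, 0)
  expect_equal(w0, drop(solve(tcrossprod(X)) %*% X %*% y))

  # regularized case: solution beats random perturbations of the quadratic
  Ls <- diag(n) - matrix(1 / n, n, n)
  Xt <- matrix(rnorm(d * n), d, n)
  Smooth <- Xt %*% tcrossprod(Ls, Xt)
  dvec <- runif(d, 0.5, 2)
  mu <- 20; beta <- 5
  w <- hlrnet:::.solveW(tcrossprod(X), Smooth, drop(X %*% y), dvec, mu, beta)
  A <- tcrossprod(X) + 2 * beta * Smooth + mu * diag(dvec)
  b <- drop(X %*% y)
  expect_lt(max(abs(A %*% w - b)), 1e-8)
  g <- function(v) drop(v %*% A %*% v - 2 * sum(v * b))
  for (i in 1:1000) {
    delta <- rnorm(d, sd = 0.1)
    expect_lte(g(w), g(w + delta) + 1e-10)
  }
})

test_that("eta weights are inverse l2,1 residual norms", {
  R <- matrix(0, 3, 4)
  R[, 1] <- c(2, 0, 0)  # column norms 2,0,0,0 -> l2,1 norm 2
  expect_equal(hlrnet:::.l21norm(R), 2)
  expect_equal(1 / (2 * hlrnet:::.l21norm(R)), 0.25)
  set.seed(16)
  A <- matrix(rnorm(30), 5, 6)
  expect_lt(abs(hlrnet:::.l21norm(A) -
                sum(vapply(1:6, function(j) sqrt(sum(A[, j]^2)), 0))), 1e-12)
})

test_that("the joint fit respects its feasibility invariants", {
  fs <- makeTinyFeatureSet(n = 20, d = 15, planted = 1:4, effect = 1.5,
                           seed = 17)
  fit <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 3)))
  S <- similarityMatrix(fit)
  y <- classLabels(fs)
  expect_equal(unname(rowSums(S)), rep(1, 20))
  expect_true(all(S[outer(y, y, "!=")] == 0))
  expect_true(all(rowSums(S > 0) <= 3))
  expect_lt(max(abs(crossprod(fit@V) - diag(2))), 1e-8)
  expect_true(all(fit@Z >= 0))
  h <- convergenceHistory(fit)
  expect_lt(h$residFactor[nrow(h)], 1e-5)
  expect_equal(dim(weightMatrix(fit)), c(15L, 2L))
})

test_that("identical modalities receive identical modality weights", {
  set.seed(18)
  X <- matrix(rnorm(12 * 14), 12, 14)
  fs <- multimodalFeatureSet(list(A = X, B = X), rep(c(1, -1), each = 7))
  fit <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 3)))
  expect_equal(unname(fit@eta[1]), unname(fit@eta[2]))
  expect_equal(weightMatrix(fit)[, 1], weightMatrix(fit)[, 2])
})

test_that("the fit is deterministic and the factorization is feasible", {
  fs <- makeTinyFeatureSet(n = 30, d = 20, planted = 1:5, effect = 1,
                           seed = 19)
  f1 <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 5)))
  f2 <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 5)))
  expect_lt(max(abs(weightMatrix(f1) - weightMatrix(f2))), 1e-10)
  for (m in 1:2) {
    R <- featureMatrices(fs)[[m]] - f1@U[[m]] %*% t(f1@V) - f1@E[[m]]
    expect_lt(sqrt(sum(R^2)) / sqrt(sum(featureMatrices(fs)[[m]]^2)), 1e-4)
  }
})

test_that("extreme group sparsity crushes the weight matrix", {
  fs <- makeTinyFeatureSet(n = 16, d = 10, seed = 20)
  fit <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 3, mu = 1e6)))
  expect_lt(sqrt(sum(weightMatrix(fit)^2)), 1e-3)
})

test_that("both readings of the spectral V-target run and stay feasible", {
  fs <- makeTinyFeatureSet(n = 16, d = 10, effect = 1, seed = 21)
  for (qs in c("stated", "scaled")) {
    fit <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 3, qSpectral = qs)))
    expect_lt(max(abs(crossprod(fit@V) - diag(2))), 1e-8)
  }
  fitRaw <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 3, latent = FALSE)))
  expect_s4_class(fitRaw, "LrmfsFit")
})

test_that("planted discriminative features rise to the top of the ranking", {
  fs <- makeTinyFeatureSet(n = 24, d = 15, planted = 1:3, effect = 2,
                           seed = 22)
  fit <- suppressWarnings(fitLRMFS(fs, lrmfsParams(K = 4)))
  sel <- selectFeatures(fit, 4)$selected
  expect_gte(length(intersect(sel, 1:3)), 2)
})

test_that("latent similarity starves outlier subjects of neighbor mass", {
  # outlier subjects should attract far less similarity mass when distances
  # are measured between denoised reconstructions than between raw samples
  ratios <- vapply(c(5L, 6L, 7L), function(s) {
    coh <- generateCohort(cohortConfig(
      nSubjectsPerClass = 15L, nRegions = 30L, nTimepoints = 40L,
      nModules = 3L, effectSize = 1.5, plantedRegions = seq(1, 29, by = 6),
      outlierFraction = 0.1, seed = s))
    out <- coh@config$outlierSubjects
    X <- list(CBF = zscoreFeatures(coh@cbf)$X)
    fs <- multimodalFeatureSet(X, coh@labels)
    fl <- suppressWarnings(fitLRMFS(fs, lrmfsParams(latent = TRUE)))
    fr <- suppressWarnings(fitLRMFS(fs, lrmfsParams(latent = FALSE)))
    massL <- mean(colSums(similarityMatrix(fl))[out])
    massR <- mean(colSums(similarityMatrix(fr))[out])
    # E absorbs the outlier columns
    eNorm <- sqrt(colSums(fl@E[[1]]^2))
    expect_gt(mean(eNorm[out]), mean(eNorm[-out]))
    massL / max(massR, 1e-12)
  }, numeric(1))
  expect_lt(mean(ratios), 1)
})

test_that("feature ranking follows row norms with fixed conventions", {
  W <- matrix(0, 5, 2)
  W[3, ] <- c(1, -2)
  sel1 <- selectFeatures(W, 1)
  expect_equal(sel1$selected, 3L)
  expect_equal(sel1$table$norm, sqrt(5))

  W2 <- matrix(c(3, 1, 2, 0, 0, 0, 0, 0, 0, 0), 5, 2)
  all5 <- selectFeatures(W2, 5)
  expect_equal(all5$selected, c(1L, 3L, 2L, 4L, 5L))
  # sign flips of whole columns do not change the ranking
  expect_equal(selectFeatures(-W2, 5)$selected, all5$selected)
  expect_error(selectFeatures(W2, 6), "topT")

  fsBad <- makeTinyFeatureSet(n = 8, d = 5, seed = 23)
  expect_error(fitLRMFS(fsBad, lrmfsParams(K = 4)), "smallest class")
})
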