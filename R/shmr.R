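#' Pearson correlation network
#'
#' Baseline functional connectivity: the Pearson correlation matrix of the
#' region columns of a timepoints x regions matrix.
#'
#' @param ts timepoints x regions numeric matrix (>= 3 rows).
#' @return symmetric regions x regions matrix, unit diagonal, entries in
#'   [-1, 1], dimnames carried over from the columns of `ts`.
#' @export
pearsonNetwork <- function(ts) {
  stopifnot(is.matrix(ts), nrow(ts) >= 3)
  v <- apply(ts, 2, sd)
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  C <- cor(ts)
  (C + t(C)) / 2
}

#' k-nearest-neighbor hypergraph from a connectivity matrix
#'
#' One hyperedge per region: the region itself plus its `knnK` most
#' correlated neighbors by absolute correlation (ties broken by ascending
#' region index). The edge weight is the mean pairwise absolute correlation
#' within the hyperedge (floored at 1e-8 to keep degrees positive).
#'
#' @param corr symmetric connectivity matrix.
#' @param knnK neighborhood size, `0 < knnK < nrow(corr)`.
#' @return a \linkS4class{Hypergraph} with `nrow(corr)` hyperedges of size
#'   `knnK + 1`.
#' @export
buildHypergraph <- function(corr, knnK = 3L) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  n <- nrow(corr)
  if (knnK <= 0) stop("knnK must be positive")
  if (knnK >= n) stop("knnK must be smaller than the number of regions")
  A <- abs(corr)
  diag(A) <- -Inf
  H <- matrix(0, n, n)
  w <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(-A[i, ], seq_len(n))[seq_len(knnK)]
    members <- c(i, nb)
    H[members, i] <- 1
    pairs <- combn(members, 2)
    w[i] <- max(mean(abs(corr[cbind(pairs[1, ], pairs[2, ])])), 1e-8)
  }
  rownames(H) <- rownames(corr)
  new("Hypergraph", incidence = H, edgeWeights = w)
}

#' Normalized hypergraph Laplacian
#'
#' Zhou-style normalization:
#' \deqn{L_h = I - D_v^{-1/2} H W_e D_e^{-1} H^T D_v^{-1/2}}
#' with vertex degrees \eqn{D_v = H w}, edge degrees \eqn{D_e} the column
#' sums of \eqn{H}. Symmetric positive semidefinite; \eqn{D_v^{1/2} 1} is a
#' null vector.
#'
#' @param hg a \linkS4class{Hypergraph}; all vertex degrees must be > 0.
#' @return symmetric PSD matrix, regions x regions.
#' @export
hypergraphLaplacian <- function(hg) {
  stopifnot(is(hg, "Hypergraph"))
  H <- hg@incidence
  dv <- vertexDegrees(hg)
  de <- edgeDegrees(hg)
  if (any(dv <= 0)) stop("isolated vertex: all vertex degrees must be > 0")
  Hs <- H * (1 / sqrt(dv))                    # D_v^{-1/2} H
  Theta <- Hs %*% (t(Hs) * (hg@edgeWeights / de))  # Hs W De^{-1} Hs^T
  L <- diag(nrow(H)) - Theta
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(H)[c(1, 1)]
  L
}

#' SHMR parameter defaults
#'
#' Sparse + hypergraph-manifold regularized network estimation parameters:
#' manifold weight lambda = 2^-3, sparsity weight gamma = 2^-4, hyperedge
#' neighborhood size 3, proximal-gradient controls.
#'
#' @param lambda manifold regularization weight (> 0 unless exactly 0).
#' @param gamma l1 sparsity weight (>= 0).
#' @param knnK hyperedge neighborhood size.
#' @param maxIter,tol solver controls.
#' @return named list.
#' @export
shmrParams <- function(lambda = 2^-3, gamma = 2^-4, knnK = 3L,
                       maxIter = 500L, tol = 1e-6) {
  stopifnot(lambda >= 0, gamma >= 0, knnK >= 1, maxIter >= 1, tol > 0)
  list(lambda = lambda, gamma = gamma, knnK = knnK,
       maxIter = maxIter, tol = tol)
}

#' SHMR objective value
#'
#' \eqn{\|P - C\|_F^2 + \lambda tr(P^T L P) + \gamma \|P\|_1} where `C` is
#' the Pearson target matrix.
#'
#' @param P candidate network matrix.
#' @param C data-fit target (Pearson matrix).
#' @param L hypergraph Laplacian.
#' @param lambda,gamma regularization weights.
#' @return scalar objective value.
#' @export
shmrObjective <- function(P, C, L, lambda, gamma) {
  sum((P - C)^2) + lambda * sum(P * (L %*% P)) + gamma * sum(abs(P))
}

.softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the sparse hypergraph-manifold regularized network
#'
#' Minimizes \eqn{\|P - Q^T Q\|_F^2 + \lambda tr(P^T L_h P) + \gamma
#' \|P\|_1} by proximal gradient (ISTA) with backtracking, where the signal
#' columns are z-scored and scaled by \eqn{1/\sqrt{T-1}} so that
#' \eqn{Q^T Q} is exactly the Pearson correlation matrix. The returned
#' matrix is symmetrized and its diagonal zeroed; the optimizer's objective
#' trace (monotone non-increasing) is attached as attribute `"objective"`,
#' and `"converged"` records whether the relative objective change dropped
#' below `tol` within `maxIter` iterations (a warning is raised otherwise).
#'
#' @param ts timepoints x regions matrix.
#' @param L hypergraph Laplacian (regions x regions); if `NULL`, built from
#'   the Pearson network of `ts` with `params$knnK`.
#' @param params list from \code{\link{shmrParams}}.
#' @return regions x regions connectivity matrix with attributes
#'   `"objective"` (per-iteration trace) and `"converged"`.
#' @export
fitSHMR <- function(ts, L = NULL, params = shmrParams()) {
  C <- pearsonNetwork(ts)
  if (is.null(L)) L <- hypergraphLaplacian(buildHypergraph(C, params$knnK))
  stopifnot(nrow(L) == nrow(C))
  lambda <- params$lambda; gamma <- params$gamma
  normL <- if (lambda > 0)
    max(abs(eigen(L, symmetric = TRUE, only.values = TRUE)$values)) else 0
  step <- 1 / (2 + 2 * lambda * normL)
  P <- C
  obj <- shmrObjective(P, C, L, lambda, gamma)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(params$maxIter)) {
    grad <- 2 * (P - C) + 2 * lambda * (L %*% P)
    s <- step
    repeat {
      Pn <- .softThreshold(P - s * grad, s * gamma)
      objn <- shmrObjective(Pn, C, L, lambda, gamma)
      if (objn <= obj + 1e-12 || s < 1e-12) break
      s <- s / 2
    }
    rel <- abs(obj - objn) / max(1, abs(obj))
    P <- Pn
    obj <- objn
    trace <- c(trace, obj)
    if (rel < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fitSHMR did not converge within ", params$maxIter,
            " iterations; returning last iterate")
  P <- (P + t(P)) / 2
  diag(P) <- 0
  dimnames(P) <- dimnames(C)
  structure(P, objective = trace, converged = converged)
}

#' Estimate SHMR networks for every subject of a cohort
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param params list from \code{\link{shmrParams}}.
#' @return list of connectivity matrices, one per subject.
#' @export
fitCohortNetworks <- function(cohort, params = shmrParams()) {
  stopifnot(is(cohort, "Cohort"))
  lapply(cohort@timeSeries, fitSHMR, L = NULL, params = params)
}
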