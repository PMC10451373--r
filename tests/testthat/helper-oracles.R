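# Independent reference implementations used as oracles. These deliberately
# take different algorithmic routes than the package code they check.

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency matrix
fwDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n)) {
      dik <- D[i, k]
      if (is.finite(dik)) {
        nd <- dik + D[k, ]
        upd <- nd < D[i, ]
        D[i, upd] <- nd[upd]
      }
    }
  D
}

fwNodalEfficiency <- function(adj) {
  D <- fwDistances(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

# Euclidean projection onto the probability simplex (sort-based algorithm)
projectSimplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# solve min_s sum(d * s) + alpha * sum(s^2) on the simplex via projection:
# argmin = proj_simplex(-d / (2 alpha))
simplexQpOracle <- function(d, alpha) projectSimplex(-d / (2 * alpha))

# the K-neighbor alpha rule (independent re-statement)
kNeighborAlpha <- function(d, K) {
  ds <- sort(d)
  (K * ds[K + 1] - sum(ds[seq_len(K)])) / 2
}

# random matrix with orthonormal columns
randomOrthonormal <- function(n, r) qr.Q(qr(matrix(rnorm(n * r), n, r)))

# random symmetric zero-diagonal binary adjacency
randomAdjacency <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# small multimodal feature set with planted rows in modality 2
makeTinyFeatureSet <- function(n = 16, d = 12, planted = 1:3, effect = 0,
                               seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  X1 <- matrix(rnorm(d * n), d, n)
  X2 <- matrix(rnorm(d * n), d, n)
  X2[planted, y > 0] <- X2[planted, y > 0] + effect
  multimodalFeatureSet(list(A = X1, B = X2), y)
}
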