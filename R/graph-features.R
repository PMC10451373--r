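#' Sparsity threshold grid
#'
#' The grid of network sparsities over which nodal efficiency is integrated:
#' 0.01 to 0.35 in steps of 0.01 by default.
#'
#' @param start,stop,step grid bounds and spacing, `0 < start <= stop < 1`.
#' @return numeric vector of sparsity values.
#' @export
sparsityGrid <- function(start = 0.01, stop = 0.35, step = 0.01) {
  stopifnot(start > 0, start <= stop, stop < 1, step > 0)
  seq(start, stop, by = step)
}

#' Binarize a network at a sparsity threshold
#'
#' Keeps the top `floor(sparsity * N(N-1)/2)` off-diagonal edges by absolute
#' weight (ties broken by ascending (i, j) lexicographic index) and sets
#' them to 1; everything else 0. Entries that are exactly zero are absent
#' connections, never edges, so an all-zero network stays empty at every
#' sparsity. Symmetric with zero diagonal.
#'
#' @param net symmetric connectivity matrix.
#' @param sparsity fraction of possible edges to keep, in (0, 1).
#' @return binary adjacency matrix.
#' @export
binarizeBySparsity <- function(net, sparsity) {
  stopifnot(is.matrix(net), nrow(net) == ncol(net))
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)")
  n <- nrow(net)
  m <- floor(sparsity * n * (n - 1) / 2)
  A <- matrix(0, n, n, dimnames = dimnames(net))
  if (m > 0) {
    idx <- which(upper.tri(net), arr.ind = TRUE)
    wt <- abs(net[idx])
    keep <- order(-wt, idx[, 1], idx[, 2])[seq_len(min(m, sum(wt > 0)))]
    A[idx[keep, , drop = FALSE]] <- 1
    A <- A + t(A)
  }
  A
}

# trapezoidal rule on an increasing grid; eff: regions x grid matrix
.trapz <- function(grid, eff) {
  if (is.null(dim(eff))) eff <- matrix(eff, nrow = 1)
  drop((eff[, -ncol(eff), drop = FALSE] +
        eff[, -1, drop = FALSE]) %*% diff(grid)) / 2
}

#' Nodal efficiency of a binary graph
#'
#' For each node \eqn{i}, \eqn{E(i) = \frac{1}{N-1}\sum_{j \ne i} 1/d(i,j)}
#' with unweighted shortest-path distances; unreachable pairs contribute 0,
#' so isolated nodes have efficiency 0.
#'
#' @param adj symmetric binary adjacency matrix with zero diagonal, N >= 2.
#' @return numeric vector of length N with entries in [0, 1].
#' @export
nodalEfficiency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  n <- nrow(adj)
  if (n < 2) stop("at least 2 nodes required")
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  setNames(rowSums(inv) / (n - 1), rownames(adj))
}

#' AUC of nodal efficiency over a sparsity grid
#'
#' Binarizes the network at every sparsity in the grid, computes nodal
#' efficiency, and integrates per region by the trapezoidal rule against
#' sparsity. Depends on the weights only through their rank order.
#'
#' @param net symmetric connectivity matrix.
#' @param grid numeric sparsity grid from \code{\link{sparsityGrid}}.
#' @return numeric vector, one AUC per region.
#' @export
aucOverSparsity <- function(net, grid = sparsityGrid()) {
  stopifnot(is.matrix(net), nrow(net) == ncol(net),
            length(grid) >= 2, all(diff(grid) > 0), grid[1] > 0,
            grid[length(grid)] < 1)
  n <- nrow(net)
  # edges ranked once; each grid level keeps a prefix of this ranking, so
  # the result matches nodalEfficiency(binarizeBySparsity(net, s)) exactly
  idx <- which(upper.tri(net), arr.ind = TRUE)
  wt <- abs(net[idx])
  ord <- order(-wt, idx[, 1], idx[, 2])
  ranked <- idx[ord, , drop = FALSE]
  counts <- pmin(floor(grid * n * (n - 1) / 2), sum(wt > 0))
  eff <- vapply(counts, function(m) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (m > 0)
      g <- igraph::add_edges(g, t(ranked[seq_len(m), , drop = FALSE]))
    d <- igraph::distances(g)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    rowSums(inv) / (n - 1)
  }, numeric(n))
  setNames(.trapz(grid, eff), rownames(net))
}

#' Z-score features across subjects
#'
#' Standardizes each feature (row) to mean 0, sd 1 across subjects
#' (columns). When `stats` from a previous (training) call is supplied, the
#' stored means/sds are applied instead, so test folds never contribute to
#' the normalization. Constant features are centered with a unit divisor
#' and flagged.
#'
#' @param X features x subjects matrix.
#' @param stats optional list from a previous call (`mean`, `sd`, `flagged`).
#' @return list with `X` (normalized matrix) and `stats`.
#' @export
zscoreFeatures <- function(X, stats = NULL) {
  stopifnot(is.matrix(X))
  if (is.null(stats)) {
    mu <- rowMeans(X)
    sdv <- apply(X, 1, sd)
    flagged <- !is.finite(sdv) | sdv <= 0
    sdv[flagged] <- 1
    stats <- list(mean = mu, sd = sdv, flagged = flagged)
  }
  list(X = (X - stats$mean) / stats$sd, stats = stats)
}

#' Assemble the two-modality feature set
#'
#' Modality "GT-hypergraph": per-subject AUC of nodal efficiency over the
#' sparsity grid, computed from the supplied networks. Modality "CBF": the
#' cohort's scalar region features. Optionally z-scored per feature across
#' all subjects (for cross-validation, leave raw and normalize per fold).
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param networks list of connectivity matrices, one per subject (e.g. from
#'   \code{\link{fitCohortNetworks}}).
#' @param grid sparsity grid.
#' @param zscore z-score globally across all subjects (default TRUE).
#' @return a \linkS4class{MultimodalFeatureSet}.
#' @export
buildFeatureSet <- function(cohort, networks, grid = sparsityGrid(),
                            zscore = TRUE) {
  stopifnot(is(cohort, "Cohort"))
  if (length(networks) != length(cohort@timeSeries))
    stop("one network per subject required")
  Xgt <- vapply(networks, aucOverSparsity, numeric(nrow(cohort@cbf)),
                grid = grid)
  dimnames(Xgt) <- dimnames(cohort@cbf)
  Xcbf <- cohort@cbf
  if (zscore) {
    Xgt <- zscoreFeatures(Xgt)$X
    Xcbf <- zscoreFeatures(Xcbf)$X
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(`GT-hypergraph` = Xgt, CBF = Xcbf),
    colData = S4Vectors::DataFrame(label = cohort@labels))
  new("MultimodalFeatureSet", se)
}

#' Construct a MultimodalFeatureSet from raw matrices
#'
#' @param X named list of features x subjects matrices (shared columns).
#' @param labels numeric +1/-1 vector, one per subject.
#' @return a \linkS4class{MultimodalFeatureSet}.
#' @export
multimodalFeatureSet <- function(X, labels) {
  stopifnot(is.list(X), length(X) >= 1)
  n <- ncol(X[[1]])
  if (!all(vapply(X, ncol, 0L) == n))
    stop("all modalities must share the subject count")
  if (length(labels) != n) stop("one label per subject required")
  if (is.null(names(X))) names(X) <- paste0("modality", seq_along(X))
  # assays must share dimnames; the first modality's win
  X <- lapply(X, function(Xi) {
    dimnames(Xi) <- dimnames(X[[1]])
    Xi
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = X, colData = S4Vectors::DataFrame(label = labels))
  new("MultimodalFeatureSet", se)
}
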