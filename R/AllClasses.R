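#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor cov sd quantile rnorm runif optimize setNames predict
#' @importFrom utils head read.delim write.table combn
NULL

#' Hypergraph incidence structure
#'
#' A hypergraph over brain regions: a binary vertex-by-edge incidence matrix
#' \eqn{H} and a positive weight per hyperedge. Vertex degrees
#' (\eqn{d_v = H w}) and edge degrees (column sums of \eqn{H}) are derived,
#' not stored.
#'
#' @slot incidence binary matrix, regions x hyperedges.
#' @slot edgeWeights positive numeric vector, one weight per hyperedge.
#' @export
setClass("Hypergraph",
  representation(incidence = "matrix", edgeWeights = "numeric"),
  validity = function(object) {
    H <- object@incidence
    w <- object@edgeWeights
    msg <- character()
    if (!all(H %in% c(0, 1))) msg <- c(msg, "incidence must be binary")
    if (length(w) != ncol(H))
      msg <- c(msg, "one edge weight per incidence column required")
    if (length(w) && any(w <= 0)) msg <- c(msg, "edge weights must be positive")
    if (ncol(H) && any(colSums(H) < 2))
      msg <- c(msg, "every hyperedge must contain at least 2 vertices")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic two-class cohort
#'
#' Container for one simulated cohort: per-subject region-by-time signal
#' matrices, a regions x subjects matrix of perfusion-like scalar features,
#' class labels in \{+1, -1\}, the indices of the planted discriminative
#' regions, and the generating configuration (including the seed).
#'
#' @slot timeSeries list of timepoints x regions matrices, one per subject.
#' @slot cbf regions x subjects numeric matrix of scalar region features.
#' @slot labels numeric vector of +1/-1 class labels, one per subject.
#' @slot groundTruthRegions integer indices of the planted regions.
#' @slot config named list echoing the full generating configuration.
#' @export
setClass("Cohort",
  representation(timeSeries = "list", cbf = "matrix", labels = "numeric",
                 groundTruthRegions = "integer", config = "list"),
  validity = function(object) {
    n <- length(object@timeSeries)
    msg <- character()
    if (ncol(object@cbf) != n)
      msg <- c(msg, "cbf must have one column per subject")
    if (length(object@labels) != n)
      msg <- c(msg, "one label per subject required")
    if (n && !all(object@labels %in% c(-1, 1)))
      msg <- c(msg, "labels must be +1/-1")
    if (length(object@groundTruthRegions) &&
        (min(object@groundTruthRegions) < 1L ||
         max(object@groundTruthRegions) > nrow(object@cbf)))
      msg <- c(msg, "groundTruthRegions out of range")
    if (length(msg)) msg else TRUE
  }
)

#' Multimodal feature set
#'
#' A \linkS4class{SummarizedExperiment} holding one assay per modality
#' (rows = regions/features, columns = subjects) and the class label in
#' \code{colData(x)$label}. All assays share dimensions; labels are +1/-1.
#'
#' @export
setClass("MultimodalFeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (length(SummarizedExperiment::assays(object)) < 1L)
      msg <- c(msg, "at least one modality assay required")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(object$label %in% c(-1, 1)))
      msg <- c(msg, "labels must be +1/-1")
    if (length(msg)) msg else TRUE
  }
)

#' Latent-relation multimodal feature selection fit
#'
#' Result of \code{\link{fitLRMFS}}: the feature weight matrix \eqn{W}
#' (features x modalities), the learned K-sparse similarity matrix \eqn{S},
#' the latent factors (per-modality bases \eqn{U^m} and shared orthonormal
#' coefficients \eqn{V}), per-modality noise matrices \eqn{E^m} and inverse
#' residual weights \eqn{\eta}, plus the objective/residual trace.
#'
#' @slot W numeric matrix, features x modalities.
#' @slot S numeric matrix, subjects x subjects, rows on the simplex.
#' @slot U list of features x r basis matrices, one per modality.
#' @slot V subjects x r orthonormal latent coefficient matrix.
#' @slot Z subjects x r nonnegative copy of V (augmented-Lagrangian).
#' @slot E list of features x subjects noise matrices.
#' @slot eta numeric modality weights.
#' @slot history data.frame with one row per iteration (objective, residuals).
#' @slot converged logical.
#' @slot params list of fitting parameters used.
#' @export
setClass("LrmfsFit",
  representation(W = "matrix", S = "matrix", U = "list", V = "matrix",
                 Z = "matrix", E = "list", eta = "numeric",
                 history = "data.frame", converged = "logical",
                 params = "list"))

#' Cross-validation report
#'
#' Per-fold and summary classification metrics (ACC, AUC, SEN, SPE, all in
#' [0, 1]) from \code{\link{crossValidate}}, together with fold assignments,
#' the hyperparameters chosen per fold, and the seed.
#'
#' @slot folds data.frame, one row per fold.
#' @slot assignments integer fold id per subject.
#' @slot seed integer seed used.
#' @export
setClass("CvReport",
  representation(folds = "data.frame", assignments = "integer",
                 seed = "integer"))
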