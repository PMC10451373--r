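#' @rdname Hypergraph-class
#' @param object,x a \linkS4class{Hypergraph}
#' @export
setGeneric("vertexDegrees", function(x) standardGeneric("vertexDegrees"))

#' @rdname Hypergraph-class
#' @export
setGeneric("edgeDegrees", function(x) standardGeneric("edgeDegrees"))

#' @rdname Hypergraph-class
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname Hypergraph-class
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname MultimodalFeatureSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname MultimodalFeatureSet-class
#' @export
setGeneric("featureMatrices", function(x) standardGeneric("featureMatrices"))

#' @rdname LrmfsFit-class
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname LrmfsFit-class
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname LrmfsFit-class
#' @export
setGeneric("convergenceHistory",
           function(x) standardGeneric("convergenceHistory"))

#' @rdname CvReport-class
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))

#' @rdname CvReport-class
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

# ---- methods -----------------------------------------------------------

#' @rdname Hypergraph-class
#' @export
setMethod("incidenceMatrix", "Hypergraph", function(x) x@incidence)

#' @rdname Hypergraph-class
#' @export
setMethod("edgeWeights", "Hypergraph", function(x) x@edgeWeights)

#' @rdname Hypergraph-class
#' @export
setMethod("vertexDegrees", "Hypergraph",
          function(x) drop(x@incidence %*% x@edgeWeights))

#' @rdname Hypergraph-class
#' @export
setMethod("edgeDegrees", "Hypergraph", function(x) colSums(x@incidence))

setMethod("show", "Hypergraph", function(object) {
  cat("Hypergraph:", nrow(object@incidence), "vertices,",
      ncol(object@incidence), "hyperedges\n")
  cat("  edge sizes:", paste(range(edgeDegrees(object)), collapse = "-"),
      " mean weight:", signif(mean(object@edgeWeights), 3), "\n")
})

setMethod("show", "Cohort", function(object) {
  n <- length(object@timeSeries)
  cat("Cohort:", n, "subjects (",
      sum(object@labels == 1), "positive /", sum(object@labels == -1),
      "control ),", nrow(object@cbf), "regions\n")
  if (n) cat("  timepoints:", nrow(object@timeSeries[[1]]),
             " planted regions:", length(object@groundTruthRegions), "\n")
})

#' @rdname MultimodalFeatureSet-class
#' @export
setMethod("classLabels", "MultimodalFeatureSet", function(x) {
  as.numeric(x$label)
})

#' @rdname MultimodalFeatureSet-class
#' @export
setMethod("featureMatrices", "MultimodalFeatureSet", function(x) {
  as.list(SummarizedExperiment::assays(x))
})

#' @rdname LrmfsFit-class
#' @export
setMethod("weightMatrix", "LrmfsFit", function(x) x@W)

#' @rdname LrmfsFit-class
#' @export
setMethod("similarityMatrix", "LrmfsFit", function(x) x@S)

#' @rdname LrmfsFit-class
#' @export
setMethod("convergenceHistory", "LrmfsFit", function(x) x@history)

setMethod("show", "LrmfsFit", function(object) {
  cat("LrmfsFit:", nrow(object@W), "features x", ncol(object@W),
      "modalities;", nrow(object@history), "iterations;",
      if (object@converged) "converged" else "NOT converged", "\n")
})

#' @rdname CvReport-class
#' @export
setMethod("cvFolds", "CvReport", function(x) x@folds)

#' @rdname CvReport-class
#' @export
setMethod("cvSummary", "CvReport", function(x) {
  m <- x@folds[, c("acc", "auc", "sen", "spe"), drop = FALSE]
  data.frame(metric = toupper(colnames(m)),
             mean = colMeans(m, na.rm = TRUE),
             sd = apply(m, 2, sd, na.rm = TRUE),
             row.names = NULL)
})

setMethod("show", "CvReport", function(object) {
  s <- cvSummary(object)
  cat("CvReport:", nrow(object@folds), "folds, seed", object@seed, "\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.2f%% +/- %.2f\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
})
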