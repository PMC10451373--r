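#' Linear Gram matrix of a feature block
#'
#' @param X features x subjects matrix.
#' @return subjects x subjects Gram matrix \eqn{X^T X}.
#' @export
linearKernel <- function(X) crossprod(X)

#' Convex combination of per-modality Gram matrices
#'
#' \eqn{K = \sum_m w_m K_m} with weights on the probability simplex;
#' positive semidefiniteness is preserved.
#'
#' @param grams list of symmetric PSD Gram matrices of equal dimension.
#' @param weights nonnegative weights summing to 1, one per Gram.
#' @return combined Gram matrix.
#' @export
combineKernels <- function(grams, weights) {
  stopifnot(is.list(grams), length(grams) >= 1)
  if (length(weights) != length(grams))
    stop("one weight per kernel required")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-8)
    stop("kernel weights must lie on the probability simplex")
  Reduce(`+`, Map(`*`, grams, weights))
}

#' Fit and predict an SVM on a precomputed kernel
#'
#' Trains a C-SVM on the training Gram matrix and scores test samples from
#' their cross-Gram with the training set. The Gram is factorized by
#' eigendecomposition into an exact finite-dimensional feature map, on
#' which libsvm with a linear kernel reproduces the kernel machine.
#'
#' @param gramTrain n x n symmetric PSD training Gram matrix.
#' @param yTrain +1/-1 labels, both classes present.
#' @param gramCross nTest x n Gram between test and training samples.
#' @param C SVM cost parameter.
#' @return list with `labels` (+1/-1 predictions) and `scores` (signed
#'   margins, positive favors class +1).
#' @export
fitPredictMKSVM <- function(gramTrain, yTrain, gramCross, C = 1) {
  n <- length(yTrain)
  stopifnot(nrow(gramTrain) == n, ncol(gramTrain) == n,
            ncol(gramCross) == n, C > 0)
  if (length(unique(yTrain)) < 2)
    stop("training fold contains a single class")
  eg <- eigen((gramTrain + t(gramTrain)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values, 0) * 1e-10
  if (!any(keep)) stop("training Gram matrix is numerically zero")
  Uk <- eg$vectors[, keep, drop = FALSE]
  dk <- eg$values[keep]
  phiTrain <- Uk * rep(sqrt(dk), each = n)
  phiTest <- gramCross %*% (Uk * rep(1 / sqrt(dk), each = n))
  .linearSvmPredict(phiTrain, yTrain, phiTest, C)
}

# linear SVM on explicit feature rows; scores oriented so + favors class +1.
# Calls libsvm through e1071's compiled entry point directly (the R wrapper
# spends ~10x the solver time on input conversion, which matters inside the
# hyperparameter grid search); falls back to the public API if unavailable.
# Equivalence with e1071::svm is asserted in the test suite.
.linearSvmPredict <- function(phiTrain, yTrain, phiTest, C) {
  if (length(unique(yTrain)) < 2)
    stop("training fold contains a single class")
  fit <- tryCatch(.svmTrainLinear(phiTrain, yTrain, C),
                  error = function(e) NULL)
  if (is.null(fit)) fit <- .svmTrainLinearSafe(phiTrain, yTrain, C)
  # linear machine: w = coefs^T SV, score = phi w - rho; libsvm orients the
  # decision value toward the first training label it encountered
  w <- drop(crossprod(fit$coefs, fit$SV))
  dv <- drop(phiTest %*% w) - fit$rho
  if (fit$firstLabel == -1) dv <- -dv
  labels <- ifelse(dv > 0, 1, -1)
  list(labels = labels, scores = dv)
}

# direct call into e1071's registered svmtrain routine: C-classification,
# linear kernel, dense inputs, no class weights / probabilities / CV
.svmTrainLinear <- function(x, y, C) {
  sym <- get("R_svmtrain", envir = asNamespace("e1071"))
  nr <- nrow(x)
  yi <- as.double(ifelse(y > 0, 2L, 1L))  # codes of factor(y, c(-1, 1))
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(sym, as.double(t(x)), as.integer(nr), as.integer(ncol(x)),
             yi, as.integer(0), as.integer(0),
             as.integer(0),            # type: C-classification
             as.integer(0),            # kernel: linear
             as.integer(3), as.double(1 / ncol(x)), as.double(0),
             as.double(C), as.double(0.5),
             integer(0), double(0), as.integer(0),
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1), as.integer(0), as.integer(0), as.integer(0),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (!identical(substr(cret$error, 1, 1), " "))
    stop(trimws(cret$error))
  idx <- cret$index[seq_len(cret$nr)]
  list(SV = x[idx, , drop = FALSE], coefs = cret$coefs[seq_len(cret$nr)],
       rho = cret$rho,
       firstLabel = c(-1, 1)[cret$labels[1]])
}

# public-API fallback, identical model
.svmTrainLinearSafe <- function(x, y, C) {
  yf <- factor(y, levels = c(-1, 1))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                    fitted = FALSE)
  list(SV = fit$SV, coefs = drop(fit$coefs), rho = fit$rho,
       firstLabel = as.numeric(levels(yf)[fit$labels[1]]))
}

#' Binary classification metrics
#'
#' ACC, sensitivity (recall of class +1), specificity (recall of class -1)
#' from hard labels, and AUC as the Mann-Whitney statistic of the scores
#' (ties count 1/2).
#'
#' @param yTrue true +1/-1 labels; both classes must be present.
#' @param yPred predicted +1/-1 labels.
#' @param scores real-valued scores, higher favors class +1.
#' @return named numeric vector (acc, sen, spe, auc), all in [0, 1].
#' @export
confusionMetrics <- function(yTrue, yPred, scores = NULL) {
  stopifnot(length(yTrue) == length(yPred))
  if (length(unique(yTrue)) < 2)
    stop("both classes must be present in yTrue")
  pos <- yTrue == 1
  tp <- sum(pos & yPred == 1)
  tn <- sum(!pos & yPred == -1)
  acc <- (tp + tn) / length(yTrue)
  sen <- tp / sum(pos)
  spe <- tn / sum(!pos)
  auc <- NA_real_
  if (!is.null(scores)) {
    sp <- scores[pos]
    sn <- scores[!pos]
    cmp <- outer(sp, sn, "-")
    auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sn))
  }
  c(acc = acc, sen = sen, spe = spe, auc = auc)
}

# enumerate simplex weight vectors of length m with the given step
.simplexGrid <- function(m, step = 0.1) {
  k <- round(1 / step)
  if (m == 1) return(matrix(1, 1, 1))
  combos <- expand.grid(rep(list(0:k), m - 1))
  combos <- combos[rowSums(combos) <= k, , drop = FALSE]
  w <- cbind(as.matrix(combos), k - rowSums(combos)) / k
  w[order(w[, 1], decreasing = TRUE), , drop = FALSE]
}

# stratified fold ids (1..nFolds), deterministic given the RNG state; the
# fold cycle continues across classes so leftover subjects spread evenly
.stratifiedFolds <- function(y, nFolds) {
  ids <- integer(length(y))
  start <- 0L
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    ids[idx] <- ((start + seq_along(idx) - 1L) %% nFolds) + 1L
    start <- start + length(idx)
  }
  ids
}

#' Cross-validated evaluation of the full selection + MKSVM pipeline
#'
#' Stratified outer folds. Within each training fold only: per-feature
#' z-scoring (stats applied to the test fold), LRMFS fitting, top-`topT`
#' feature selection, and an inner stratified cross-validation choosing the
#' kernel fusion weights (simplex grid, step 0.1) and the SVM cost C
#' (powers of two, 2^-5 ... 2^5) by mean inner accuracy (ties resolved by
#' grid order). Per-modality kernels are linear on the selected features;
#' the convex kernel combination is realized exactly as a linear SVM on
#' sqrt-weight-scaled stacked features.
#'
#' @param x a \linkS4class{MultimodalFeatureSet} with raw (non-normalized)
#'   features.
#' @param params LRMFS parameters from \code{\link{lrmfsParams}}.
#' @param nFolds outer folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param topT features kept per fold (default 15).
#' @param costGrid SVM cost grid.
#' @param weightStep kernel weight grid step on the simplex.
#' @param innerFolds inner folds for hyperparameter selection (default 5).
#' @return a \linkS4class{CvReport}.
#' @export
crossValidate <- function(x, params = lrmfsParams(), nFolds = 10L,
                          seed = 1L, topT = 15L, costGrid = 2^(-5:5),
                          weightStep = 0.1, innerFolds = 5L) {
  stopifnot(is(x, "MultimodalFeatureSet"))
  X <- featureMatrices(x)
  y <- classLabels(x)
  n <- length(y)
  if (n < nFolds) stop("more folds than subjects")
  set.seed(as.integer(seed))
  foldId <- .stratifiedFolds(y, nFolds)
  wGrid <- .simplexGrid(length(X), weightStep)
  rows <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    tr <- which(foldId != f)
    te <- which(foldId == f)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
      stop("a class is absent from fold ", f, "; lower nFolds")
    Xtr <- Xte <- vector("list", length(X))
    for (m in seq_along(X)) {
      z <- zscoreFeatures(X[[m]][, tr, drop = FALSE])
      Xtr[[m]] <- z$X
      Xte[[m]] <- zscoreFeatures(X[[m]][, te, drop = FALSE], z$stats)$X
    }
    names(Xtr) <- names(Xte) <- names(X)
    fsTr <- multimodalFeatureSet(Xtr, y[tr])
    fit <- suppressWarnings(fitLRMFS(fsTr, params))
    sel <- selectFeatures(fit, topT)$selected
    selTr <- lapply(Xtr, function(Xi) Xi[sel, , drop = FALSE])
    selTe <- lapply(Xte, function(Xi) Xi[sel, , drop = FALSE])
    best <- .innerGridSearch(selTr, y[tr], wGrid, costGrid, innerFolds)
    phiTr <- .fuseFeatures(selTr, best$w)
    phiTe <- .fuseFeatures(selTe, best$w)
    pred <- .linearSvmPredict(t(phiTr), y[tr], t(phiTe), best$C)
    met <- confusionMetrics(y[te], pred$labels, pred$scores)
    rows[[f]] <- data.frame(fold = f, n = length(te), acc = met["acc"],
                            auc = met["auc"], sen = met["sen"],
                            spe = met["spe"], C = best$C,
                            w1 = best$w[1], row.names = NULL)
  }
  new("CvReport", folds = do.call(rbind, rows),
      assignments = as.integer(foldId), seed = as.integer(seed))
}

# stack sqrt-weighted modalities: linear kernel of the result equals the
# convex combination of per-modality linear kernels
.fuseFeatures <- function(Xsel, w) {
  do.call(rbind, Map(function(Xi, wi) sqrt(wi) * Xi, Xsel, as.list(w)))
}

.innerGridSearch <- function(Xsel, y, wGrid, costGrid, innerFolds) {
  innerId <- .stratifiedFolds(y, innerFolds)
  bestAcc <- -1
  best <- list(w = wGrid[1, ], C = costGrid[1])
  for (wi in seq_len(nrow(wGrid))) {
    phi <- .fuseFeatures(Xsel, wGrid[wi, ])
    for (C in costGrid) {
      accs <- numeric(innerFolds)
      ok <- TRUE
      for (g in seq_len(innerFolds)) {
        tr <- innerId != g
        if (length(unique(y[tr])) < 2 || !any(!tr)) { ok <- FALSE; break }
        pred <- .linearSvmPredict(t(phi[, tr, drop = FALSE]), y[tr],
                                  t(phi[, !tr, drop = FALSE]), C)
        accs[g] <- mean(pred$labels == y[!tr])
      }
      if (ok && mean(accs) > bestAcc + 1e-12) {
        bestAcc <- mean(accs)
        best <- list(w = wGrid[wi, ], C = C)
      }
    }
  }
  best
}
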