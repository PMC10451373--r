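#' Build a modular (block) correlation matrix, optionally perturbed
#'
#' Constructs an SPD correlation-like matrix with `nModules` equal blocks:
#' `withinCorr` inside blocks, `betweenCorr` outside, unit diagonal. Every
#' off-diagonal entry in a row or column of `perturbedRegions` is shifted by
#' `effectSize` and clipped to (-0.99, 0.99). If the result is not positive
#' definite it is ridge-lifted, `M <- (M + r I)/(1 + r)`, with the smallest
#' ridge `r <= 0.1` that works; larger requirements are an error.
#'
#' @param nRegions number of regions (matrix dimension).
#' @param nModules number of community blocks.
#' @param withinCorr,betweenCorr correlations inside/outside blocks,
#'   absolute value below 1; `withinCorr > betweenCorr` expected.
#' @param perturbedRegions integer indices whose rows/columns are shifted.
#' @param effectSize additive shift applied to perturbed entries.
#' @return SPD numeric matrix with unit diagonal.
#' @export
makeModularCovariance <- function(nRegions, nModules = 1L,
                                  withinCorr = 0.3, betweenCorr = 0.05,
                                  perturbedRegions = integer(),
                                  effectSize = 0) {
  stopifnot(nRegions >= 1, nModules >= 1, nModules <= nRegions,
            abs(withinCorr) < 1, abs(betweenCorr) < 1)
  module <- rep(seq_len(nModules), length.out = nRegions)
  module <- sort(module)  # contiguous equal-ish blocks
  M <- matrix(betweenCorr, nRegions, nRegions)
  same <- outer(module, module, "==")
  M[same] <- withinCorr
  diag(M) <- 1
  if (length(perturbedRegions) && effectSize != 0) {
    stopifnot(all(perturbedRegions >= 1), all(perturbedRegions <= nRegions))
    touch <- matrix(FALSE, nRegions, nRegions)
    touch[perturbedRegions, ] <- TRUE
    touch[, perturbedRegions] <- TRUE
    diag(touch) <- FALSE
    M[touch] <- pmin(0.99, pmax(-0.99, M[touch] + effectSize))
  }
  M <- (M + t(M)) / 2
  ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    r <- min(0.1, -ev + 1e-6)
    M2 <- (M + r * diag(nRegions)) / (1 + r)
    ev2 <- min(eigen(M2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 <= 0)
      stop("covariance cannot be made positive definite with ridge <= 0.1")
    M <- M2
  }
  M
}

#' Draw a Gaussian region-by-time signal matrix
#'
#' Timepoints are i.i.d. draws from N(0, cov); rows are timepoints, columns
#' are regions. The sample covariance converges to `cov` as the number of
#' timepoints grows.
#'
#' @param cov SPD covariance matrix (regions x regions).
#' @param nTimepoints number of rows to draw (>= 1).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return timepoints x regions numeric matrix.
#' @export
generateTimeSeries <- function(cov, nTimepoints, seed) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov), nTimepoints >= 1)
  R <- tryCatch(chol(cov), error = function(e)
    stop("covariance matrix is not positive definite"))
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(nTimepoints * nrow(cov)), nTimepoints, nrow(cov))
  X <- Z %*% R
  colnames(X) <- colnames(cov)
  X
}

#' Default cohort configuration
#'
#' Study-scale defaults: 44 subjects per class, 90 regions (AAL-style
#' parcellation), 230 timepoints (an 8-minute acquisition at TR = 2 s minus
#' ten discarded volumes), six community blocks, within/between correlations
#' 0.3/0.05, ten planted regions spread evenly across the parcellation,
#' effect size 1.5, unit feature noise, no outliers.
#'
#' @param ... overrides for any field.
#' @return named list validated for \code{\link{generateCohort}}.
#' @export
cohortConfig <- function(...) {
  cfg <- list(
    nSubjectsPerClass = 44L, nRegions = 90L, nTimepoints = 230L,
    nModules = 6L, withinCorr = 0.3, betweenCorr = 0.05,
    plantedRegions = NULL, nPlanted = 10L, effectSize = 1.5,
    connShiftScale = 0.02, noiseSd = 1, outlierFraction = 0,
    outlierScale = 3, outlierMode = "vector", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown cohort config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$plantedRegions))
    cfg$plantedRegions <-
      unique(round(seq(1, cfg$nRegions, length.out = cfg$nPlanted)))
  cfg$plantedRegions <- as.integer(cfg$plantedRegions)
  with(cfg, stopifnot(
    nSubjectsPerClass >= 1, nRegions >= 2, nTimepoints >= 3,
    withinCorr > betweenCorr, abs(withinCorr) < 1, abs(betweenCorr) < 1,
    effectSize >= 0, noiseSd >= 0, outlierFraction >= 0, outlierFraction < 1,
    outlierScale >= 1,
    all(plantedRegions >= 1), all(plantedRegions <= nRegions)))
  cfg
}

#' Generate a synthetic two-class cohort
#'
#' Class +1 (the impaired group) subjects are drawn from a modular
#' covariance whose entries touching the planted regions are shifted by
#' `effectSize * connShiftScale`, and their scalar region features get a
#' mean shift of `effectSize * noiseSd` on the planted regions. Class -1
#' subjects are drawn from the unperturbed baseline. A fraction of subjects
#' (chosen at random across both classes) have their whole feature vector
#' scaled by `outlierScale` (`outlierMode = "vector"`) or a random third of
#' entries scaled (`"entrywise"`).
#'
#' @param config list from \code{\link{cohortConfig}}.
#' @return a \linkS4class{Cohort}; fully reproducible from config + seed.
#' @export
generateCohort <- function(config = cohortConfig()) {
  cfg <- do.call(cohortConfig, config)  # re-validate
  regions <- sprintf("R%03d", seq_len(cfg$nRegions))
  covNeg <- makeModularCovariance(cfg$nRegions, cfg$nModules, cfg$withinCorr,
                                  cfg$betweenCorr)
  covPos <- makeModularCovariance(cfg$nRegions, cfg$nModules, cfg$withinCorr,
                                  cfg$betweenCorr, cfg$plantedRegions,
                                  cfg$effectSize * cfg$connShiftScale)
  dimnames(covNeg) <- dimnames(covPos) <- list(regions, regions)
  n <- 2L * cfg$nSubjectsPerClass
  labels <- rep(c(1, -1), each = cfg$nSubjectsPerClass)

  set.seed(as.integer(cfg$seed))
  subSeeds <- sample.int(2^31 - 2L, n + 2L)
  ts <- vector("list", n)
  for (i in seq_len(n))
    ts[[i]] <- generateTimeSeries(if (labels[i] > 0) covPos else covNeg,
                                  cfg$nTimepoints, subSeeds[i])

  set.seed(subSeeds[n + 1L])
  cbf <- matrix(rnorm(cfg$nRegions * n, sd = cfg$noiseSd), cfg$nRegions, n,
                dimnames = list(regions, sprintf("S%03d", seq_len(n))))
  cbf[cfg$plantedRegions, labels > 0] <-
    cbf[cfg$plantedRegions, labels > 0] + cfg$effectSize * cfg$noiseSd

  if (cfg$outlierFraction > 0) {
    set.seed(subSeeds[n + 2L])
    nOut <- floor(cfg$outlierFraction * n)
    idx <- sample.int(n, nOut)
    if (identical(cfg$outlierMode, "vector")) {
      cbf[, idx] <- cbf[, idx] * cfg$outlierScale
    } else {
      for (j in idx) {
        hit <- sample.int(cfg$nRegions, max(1L, cfg$nRegions %/% 3L))
        cbf[hit, j] <- cbf[hit, j] * cfg$outlierScale
      }
    }
    cfg$outlierSubjects <- sort(idx)
  }
  new("Cohort", timeSeries = ts, cbf = cbf, labels = labels,
      groundTruthRegions = sort(unique(cfg$plantedRegions)), config = cfg)
}

#' Write a cohort to a directory of TSV files
#'
#' Writes `ts_subject<i>.tsv` (timepoints x regions, region-ID header),
#' `cbf.tsv` (regions x subjects), `labels.tsv` and `truth_regions.tsv`.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort@timeSeries))
    writeMatrixTSV(cohort@timeSeries[[i]],
                   file.path(dir, sprintf("ts_subject%d.tsv", i)))
  writeMatrixTSV(cohort@cbf, file.path(dir, "cbf.tsv"))
  write.table(data.frame(label = cohort@labels),
              file.path(dir, "labels.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(region = cohort@groundTruthRegions),
              file.path(dir, "truth_regions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
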