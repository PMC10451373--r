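#' Full pipeline configuration
#'
#' Bundles the parameter blocks of every stage with their published
#' defaults: network estimation (lambda = 2^-3, gamma = 2^-4, knn 3),
#' sparsity grid 0.01-0.35 step 0.01, feature selection (K = 7, mu = 20,
#' beta = 5), ten-fold cross-validation and top-15 region ranking. Unknown
#' keys are rejected.
#'
#' @param cohort cohort configuration (see \code{\link{cohortConfig}}).
#' @param shmr network parameters (see \code{\link{shmrParams}}).
#' @param grid sparsity grid (see \code{\link{sparsityGrid}}).
#' @param lrmfs selection parameters (see \code{\link{lrmfsParams}}).
#' @param nFolds,topT evaluation controls.
#' @param seed master seed; all stage randomness derives from it.
#' @param outDir output directory (`NULL`: nothing written).
#' @param verbose log stage progress.
#' @return named list configuration.
#' @export
runConfig <- function(cohort = cohortConfig(), shmr = shmrParams(),
                      grid = sparsityGrid(), lrmfs = lrmfsParams(),
                      nFolds = 10L, topT = 15L, seed = 1L, outDir = NULL,
                      verbose = TRUE) {
  list(cohort = cohort, shmr = shmr, grid = grid, lrmfs = lrmfs,
       nFolds = as.integer(nFolds), topT = as.integer(topT),
       seed = as.integer(seed), outDir = outDir, verbose = isTRUE(verbose))
}

.stageLog <- function(verbose, ...) if (verbose) message("[hlrnet] ", ...)

#' Run the end-to-end pipeline
#'
#' simulate -> estimate networks -> extract features -> select features on
#' the full cohort (region ranking) -> cross-validated classification.
#' When `outDir` is set, writes per-subject networks, both feature
#' matrices, labels, `weights.tsv`, `ranked_regions.tsv`, `report.json`
#' and the resolved `config.json`. Deterministic given the seed.
#'
#' @param config list from \code{\link{runConfig}}.
#' @return list with `cohort`, `networks`, `features`, `fit`, `ranking`,
#'   `report` (a \linkS4class{CvReport}) and `summary` (metrics in percent).
#' @export
runPipeline <- function(config = runConfig()) {
  v <- config$verbose
  config$cohort$seed <- config$seed
  .stageLog(v, "simulate: ", 2 * config$cohort$nSubjectsPerClass,
            " subjects, ", config$cohort$nRegions, " regions, effect ",
            config$cohort$effectSize)
  cohort <- generateCohort(config$cohort)
  .stageLog(v, "network: SHMR lambda=", config$shmr$lambda, " gamma=",
            config$shmr$gamma, " knn=", config$shmr$knnK)
  networks <- fitCohortNetworks(cohort, config$shmr)
  .stageLog(v, "features: nodal-efficiency AUC over ", length(config$grid),
            " sparsities + CBF")
  features <- buildFeatureSet(cohort, networks, config$grid, zscore = FALSE)
  .stageLog(v, "select: LRMFS K=", config$lrmfs$K, " mu=", config$lrmfs$mu,
            " beta=", config$lrmfs$beta, " on the full cohort")
  fsAll <- multimodalFeatureSet(lapply(featureMatrices(features),
                                       function(Xi) zscoreFeatures(Xi)$X),
                                classLabels(features))
  fit <- suppressWarnings(fitLRMFS(fsAll, config$lrmfs))
  ranking <- selectFeatures(fit, config$topT)
  .stageLog(v, "classify: ", config$nFolds, "-fold stratified CV")
  report <- crossValidate(features, config$lrmfs, nFolds = config$nFolds,
                          seed = config$seed, topT = config$topT)
  summ <- cvSummary(report)
  summ$mean <- 100 * summ$mean
  summ$sd <- 100 * summ$sd

  if (!is.null(config$outDir)) {
    dir <- config$outDir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(dir, "cohort"))
    netDir <- file.path(dir, "networks")
    dir.create(netDir, showWarnings = FALSE)
    for (i in seq_along(networks))
      writeMatrixTSV(networks[[i]],
                     file.path(netDir, sprintf("net_subject%d.tsv", i)))
    fm <- featureMatrices(features)
    writeMatrixTSV(fm[[1]], file.path(dir, "X_gt.tsv"))
    writeMatrixTSV(fm[[2]], file.path(dir, "X_cbf.tsv"))
    writeMatrixTSV(weightMatrix(fit), file.path(dir, "weights.tsv"))
    write.table(ranking$table, file.path(dir, "ranked_regions.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    cfgOut <- config
    cfgOut$grid <- as.numeric(cfgOut$grid)
    jsonlite::write_json(cfgOut, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(
      list(summary = summ, folds = cvFolds(report), seed = config$seed),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
    .stageLog(v, "outputs written to ", dir)
  }
  list(cohort = cohort, networks = networks, features = features,
       fit = fit, ranking = ranking, report = report, summary = summ)
}
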