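# Shared scaled-down end-to-end experiments, memoised so that the
# acceptance checks and the generator property tests reuse identical runs.
# Experiment cohorts: 50 subjects (25/class), 90 regions, 120 timepoints,
# 10 planted regions; hyperparameter search uses a coarsened grid
# (weight step 0.25, cost 2^{-5,-3,...,5}) to keep the suite desk-scale.

.expEnv <- new.env(parent = emptyenv())

experimentFeatures <- function(effect, seed, outlierFraction = 0) {
  key <- sprintf("feat_%g_%d_%g", effect, seed, outlierFraction)
  if (is.null(.expEnv[[key]])) {
    coh <- generateCohort(cohortConfig(
      nSubjectsPerClass = 25L, nTimepoints = 120L, effectSize = effect,
      outlierFraction = outlierFraction, seed = seed))
    nets <- fitCohortNetworks(coh)
    .expEnv[[key]] <- list(
      features = buildFeatureSet(coh, nets, zscore = FALSE),
      truth = coh@groundTruthRegions)
  }
  .expEnv[[key]]
}

experimentAccuracy <- function(effect, seed, outlierFraction = 0,
                               latent = TRUE) {
  key <- sprintf("acc_%g_%d_%g_%d", effect, seed, outlierFraction, latent)
  if (is.null(.expEnv[[key]])) {
    ef <- experimentFeatures(effect, seed, outlierFraction)
    rep <- crossValidate(ef$features, lrmfsParams(latent = latent),
                         nFolds = 10L, seed = seed,
                         costGrid = 2^seq(-5, 5, by = 2), weightStep = 0.25)
    .expEnv[[key]] <- cvSummary(rep)$mean[1]
  }
  .expEnv[[key]]
}
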