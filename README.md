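# hlrnet

Multimodal classification of brain-network phenotypes with hypergraph
latent relations.

## The problem

Cognitive impairment associated with end-stage renal disease (and related
conditions) is studied with two complementary imaging modalities: the
functional connectivity structure of resting-state signals, and per-region
cerebral blood flow. Classifying patients against controls from such data
raises three coupled problems that this package addresses jointly:

1. **Network estimation that keeps high-order structure.** Per subject, a
   connectivity matrix `P` is estimated from the region-by-time signal
   matrix by minimizing

   ```
   || P - C ||_F^2  +  lambda * tr(P' L_h P)  +  gamma * || P ||_1
   ```

   where `C` is the Pearson correlation matrix, `L_h` the normalized
   Laplacian of a k-nearest-neighbor hypergraph over regions (multi-way,
   not just pairwise, relations), `lambda = 2^-3`, `gamma = 2^-4`. Each
   network is summarized per region by the area under the nodal-efficiency
   curve over binarization sparsities 0.01–0.35 (step 0.01).

2. **Feature selection that resists noise and outliers.** The
   latent-relation method jointly learns: a feature weight matrix `W`
   (rows = regions, columns = modalities) under an l2,1 group penalty
   (`mu = 20`); an adaptive K-sparse similarity matrix `S` over subjects
   (`K = 7`, rows on the probability simplex, zero across classes,
   smoothness weight `beta = 5`); and orthogonal semi-nonnegative latent
   factors `U^m, V` whose reconstruction replaces the raw features in the
   similarity — so outlying subjects are absorbed by explicit noise terms
   `E^m` instead of distorting the neighborhood structure. Regions are
   ranked by row norms of `W`; the top 15 are the discriminative regions.

3. **Multi-kernel evaluation.** Selected features from both modalities are
   fused as a convex combination of linear kernels in an SVM, with fusion
   weights and cost chosen by nested grid search inside stratified
   ten-fold cross-validation (ACC / AUC / SEN / SPE).

Because the clinical cohorts such studies use are not publicly
distributable, the package includes a synthetic cohort generator with
planted discriminative regions (44+44 subjects, 90 regions by default);
every result below is computed on it.

## Worked example

```r
library(hlrnet)

cfg <- runConfig(
  cohort = cohortConfig(nSubjectsPerClass = 15L, nTimepoints = 120L,
                        effectSize = 1.5, seed = 3L),
  seed = 3L, verbose = FALSE)
res <- runPipeline(cfg)

res$summary
#>   metric mean       sd
#> 1    ACC   90 16.10153
#> 2    AUC   95 15.81139
#> 3    SEN   85 33.74743
#> 4    SPE   90 31.62278

head(res$ranking$table, 5)
#>   rank feature name       norm w_GT-hypergraph      w_CBF
#> 1    1      21 R021 0.20281080      0.11003474 0.17036601
#> 2    2      31 R031 0.16078928      0.13713364 0.08394974
#> 3    3      90 R090 0.11084300      0.07498736 0.08162761
#> 4    4       1 R001 0.08703430      0.04941696 0.07164450
#> 5    5      11 R011 0.08318982      0.06006778 0.05755352

intersect(res$ranking$selected, res$cohort@groundTruthRegions)
#>  [1] 21 31 90  1 11 70 50 60 80 41
```

A 30-subject cohort with ten planted regions (effect size 1.5 standard
deviations, regions 1, 11, ..., 90) yields 90% cross-validated accuracy,
and all ten planted regions appear in the top-15 ranking. Per-fold
standard deviations are large because each test fold holds only three
subjects.

The pipeline writes `weights.tsv`, `ranked_regions.tsv`, per-subject
networks, both feature matrices, `report.json`, and the resolved
`config.json` when `outDir` is set. A command-line front end with
`simulate / network / features / select / classify / run-all` subcommands
is installed at `inst/cli/hlrnet.R`.

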