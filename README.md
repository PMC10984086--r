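# gcniche

Quantitative analysis of germinal-center (GC) dark-zone / light-zone
compartmentalization, for computational biologists studying how the GC dark
zone (DZ) excludes T cells and how DZ-like transcriptional and chromatin
programs reappear in aggressive B-cell lymphoma.

The GC splits into a dark zone, where B cells proliferate and hypermutate,
and a light zone (LZ), where they are selected. The two compartments differ
in T-cell content and in nuclear chromatin compaction despite lacking any
physical barrier. `gcniche` packages the statistical machinery for this
biology, exercised end-to-end on synthetic data with planted ground truth:

* **Spatial segregation.** For query cells A and reference cells B with
  positions fixed, the nearest-neighbour distances d(aᵢ, B) are compared
  against a null built by permuting the A/B labels over the pooled
  positions. The primary p-value is a calibrated two-sided permutation p on
  the median A→B distance, `p = 2 · min tail` of
  `(1 + #{median* ≷ median_obs}) / (1 + n_perm)`; segregation is called
  when the observed median exceeds the null median.
* **Interface geometry.** The DZ region is an alpha-shape-like
  morphological closing of the DZ point cloud; the DZ/LZ interface is its
  outward-facing contour, with signed distances (negative on the DZ side),
  a 100 µm band, per-phenotype density profiles and range-normalized
  distances with a close/distant cut at 0.4.
* **Chrometric classification.** Per-nucleus DNA-stain features (minimum
  intensity, 80/20 percentile ratio, HC/EC ratio = |pixels > mean + k·SD| /
  |rest|, entropy, morphology) feed a random-forest DZ/LZ classifier
  evaluated by stratified 10-fold cross-validation; mean accuracy is tested
  against the no-information rate with an exact one-sided Wilcoxon
  signed-rank test over folds.
* **Signatures.** Paired DZ−LZ differences are tested with a moderated t:
  posterior variance `(d₀s₀² + d_g s_g²)/(d₀ + d_g)` with `(d₀, s₀²)` from
  method-of-moments on log gene variances, BH-adjusted. Signature scoring
  (mean-z or total), tertile stratification, a weighted running-sum
  enrichment score with gene-permutation p, and a cross-cohort analysis
  counting in how many cohorts each DZ gene correlates negatively with a
  T-cell score complete the expression side.

All generators record their latents (true compartments, planted DE genes,
per-nucleus heterochromatin fractions, latent T-cell fractions), so every
claim is tested against a known answer.

## Worked example

```r
library(gcniche)

## a synthetic GC: B cells uniform, T cells thinned inside the DZ
sim <- simulateGCMap(TissueSimConfig(seed = 1))
sim$map
#> CellMap with 1615 cells inside a 256 -vertex GC polygon
#>   phenotypes: B_DZ (715), B_LZ (785), gdT (14), T (101)

## are T cells segregated from DZ B cells?
nnRandomizationTest(sim$map, "T", "B_DZ", nPerm = 199, seed = 1)
#> Nearest-neighbour randomization test (T -> B_DZ)
#>   observed median 101.92 um vs null median 8.42 um (199 perms)
#>   direction: segregation; permutation p = 0.01; pooled rank-sum p = 3.39e-36
```

T cells sit a median 102 µm from the nearest DZ B cell while label-shuffled
maps put them at 8 µm: the DZ repels T cells, and p = 0.01 is the smallest
value 199 permutations can resolve.

```r
## render nuclei with a planted chromatin-compaction gap and classify
grid <- gridCellMap(100, 100, spacing = 30)
img <- simulateNucleiImage(grid, NucleiSimConfig(seed = 1))
feats <- extractChrometricFeatures(img@image, img@mask, pixelSize = 0.5)
feats$label <- img@nuclei$compartment_true
tab <- feats[!feats$flagged, c("label", chrometricFeatureNames())]
runStratifiedCV(tab, k = 10, seed = 1)
#> 10-fold stratified CV: Acc = 0.995 (NIR = 0.500, signed-rank p = 0.000977)
#>   mean row-normalized confusion matrix:
#>        DZ   LZ
#>   DZ 0.99 0.01
#>   LZ 0.00 1.00

head(featureImportanceRanking(trainForest(tab, seed = 1)), 3)
#>         feature importance
#> 1 min_intensity  0.2857603
#> 2 ratio_p80_p20  0.2726500
#> 3   hc_ec_ratio  0.1881746
```

With a planted heterochromatin-fraction gap (0.35 vs 0.15) the forest
separates DZ from LZ nuclei almost perfectly, and the top discriminators
are the chromatin-compaction features: the minimum DNA intensity and the
80-to-20 intensity percentile ratio. The signed-rank p of 1/1024 says all
ten fold accuracies beat the 0.5 no-information rate.

The full chain — simulation, chrometrics, classification, spatial
statistics, signature analyses — runs from one configuration:

```r
runPipeline(system.file("extdata", "demo-config.yaml", package = "gcniche"),
            "demo-out")
```

A thin CLI wrapper with the same entry points ships in
`inst/scripts/gcniche`.

## Methods

The models, parameter choices, numerical conventions and limitations are
documented in `vignettes/gcniche-methods.Rmd`.
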