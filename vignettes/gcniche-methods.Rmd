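---
title: "Models and methods behind gcniche"
author: "gcniche maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind gcniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

The germinal center (GC) is split into a dark zone (DZ), where B cells
proliferate and hypermutate their immunoglobulin genes, and a light zone
(LZ), where they are selected. The two compartments differ in T-cell
content, transcriptional programs and nuclear chromatin compaction even
though no physical barrier separates them. `gcniche` implements the
quantitative machinery needed to study this compartmentalization:

* synthetic generators for GC point patterns, nuclear-stain images and
  expression designs with planted, recorded ground truth;
* nuclear segmentation and per-nucleus *chrometric* (chromatin +
  morphology) feature extraction, including the
  heterochromatin-to-euchromatin (HC/EC) ratio;
* a random-forest DZ/LZ nucleus classifier with stratified
  cross-validation, a no-information-rate (NIR) signed-rank test, and
  impurity-based feature importances;
* nearest-neighbour randomization tests for cell segregation and
  aggregation, DZ/LZ interface delineation with signed-distance bands,
  density profiles, and range-normalized distances;
* permutation/bootstrap correlation inference;
* paired moderated-t differential expression, signature scoring, tertile
  stratification, a running-sum enrichment score, and cross-cohort
  gene-versus-T-cell correlation analysis;
* a reproducible pipeline runner chaining all stages.

Because every generator records its latent truth, every downstream claim in
the test suite is checked against a known answer rather than against
previously published output.

# Synthetic tissue model

`simulateGCMap()` draws a GC as a disc (default radius 350 µm, a mid-sized
tonsillar GC) split by a vertical chord into a DZ (left) and LZ (right) of
configurable area fraction (default 1/2). B cells (default 1,500) are
uniform over the GC and carry marker-level phenotypes `B_DZ` / `B_LZ`,
mirroring AID+ and EGR1+ identities. T cells come from a homogeneous
Poisson process (default intensity 5×10⁻⁴ /µm², about 190 cells) and are
then independently thinned inside the DZ with retention probability
`dz_t_retention` (default 0.2). Thinning was chosen over pairwise-
interaction (Gibbs) processes because its expectations are closed-form —
the DZ T-cell count has mean `retention × intensity × DZ area`, which the
test suite verifies by Monte Carlo — while still producing the repulsive
patterns seen in stained sections. γδT-like cells use a DZ intensity
multiplier instead (they are enriched, not excluded, in the DZ). All
randomness flows from one top-level seed through named sub-streams, so
each stage can be re-run independently and reproduces bit-identically.

# Synthetic nuclei and what the chrometric features measure

`simulateNucleiImage()` renders each cell as a disc-shaped nucleus
(default radius 10 µm at 0.5 µm/px) with a three-phase intensity model of
chromatin compaction in a DNA stain:

* a constant euchromatin baseline;
* bright heterochromatin foci — non-overlapping discs covering area
  fraction `f_hc` (default 0.35 for DZ nuclei, 0.15 for LZ) at twice the
  baseline intensity;
* dark interchromatin voids — DNA-depleted channels covering
  `0.5 × f_hc` of the area whose intensity falls as `(1 − f_hc)^5`, so
  deeper compaction produces darker voids.

Each nucleus is additionally scaled by a log-normal staining-efficiency
factor (CV 0.3) and pixel noise is added. The design deliberately places
the class signal in the *extremes* of the intensity distribution rather
than its bulk: more compacted nuclei have a dimmer floor (lower minimum
DNA intensity) and a wider spread (higher 80-to-20 percentile ratio),
while per-nucleus staining variability makes raw location statistics
(mean, raw percentiles) unreliable across nuclei — as in real slides,
where absolute intensities are not comparable. This is what makes the
minimum DNA intensity and the 80/20 percentile ratio the informative
compaction readouts.

The renderer refuses overlapping nuclei (naming the colliding pair),
records the rendered HC pixel fraction per nucleus as ground truth
(within rasterization tolerance ±0.02 at radius ≥ 20 px), and writes
16-bit single-channel TIFFs with integer label masks.

The feature table produced by `extractChrometricFeatures()` reports, per
nucleus: min/max/mean/SD intensity, histogram entropy, the p20/p50/p80
percentiles (linear interpolation on sorted pixel values — the same
convention everywhere in the package), the `ratio_p80_p20`, the HC/EC
ratio, and morphology (area, perimeter, equivalent radius, circularity,
eccentricity, aspect ratio, solidity). Intensities are min-max normalized
per image first, which makes features invariant to padding with
background and comparable across images. Nuclei under 10 pixels are
flagged and get missing features.

The *classifier registry* (`chrometricFeatureNames()`) is a fixed
14-feature subset: it keeps the two compaction features named above plus
standard texture and morphology, but excludes the raw p20/p50/p80
percentiles — location statistics confounded with staining/illumination —
in favour of their scale-free ratio. The registry is one function, so
features can be added without touching callers.

The HC/EC ratio uses a per-nucleus adaptive threshold: HC pixels are
those brighter than `mean + k·SD` (default `k = 1`) of that nucleus's own
pixels, and the ratio is |HC| / |EC|. Per-nucleus thresholding avoids
inter-image illumination confounds and is invariant to affine intensity
rescaling; a nucleus with no pixel above threshold (or zero spread)
returns 0 and is flagged. The estimator is a declared choice — the ratio
is standard, its estimator is not fixed by convention.

# DZ/LZ classifier

`runStratifiedCV()` z-scores the features, builds stratified folds
preserving class ratios, and trains one random forest per fold (defaults:
500 trees, √p features per split, unlimited depth; all exposed).
Confusion matrices are computed on held-out folds, row-normalized, then
averaged — normalize-then-average is the declared order. The NIR is the
majority-class prior (exactly 0.5 for balanced input). Fold accuracies
are compared to the NIR by `nirWilcoxonTest()`, a one-sided signed-rank
test that drops zero differences, uses the exact null for up to 25
untied folds (all ten folds above the NIR gives p = 1/1024 ≈ 0.000977),
enumerates all sign patterns exactly when ties are present and the fold
count is small, and otherwise applies a tie-corrected normal
approximation. `balancedSubsample()` equalizes class counts without
replacement before training, and `holdoutSpatialPrediction()` predicts
every cell with a forest that never saw it, joined back to map
coordinates.

On the default synthetic fixture the classifier is essentially perfect
(accuracy ≈ 1 at an f_hc gap of 0.2), which is higher than one would see
on real stained tissue; the synthetic render contains no segmentation
errors, no partial nuclei, no out-of-focus light and no biological
within-class heterogeneity beyond the staining factor. Passing tests
therefore demonstrate correctness of the machinery and the direction and
orderings of effects, not field-realistic accuracy values.

# Randomization test for segregation and aggregation

`nnRandomizationTest()` measures the nearest-neighbour (NN) distances
from each query (A) cell to the reference (B) population and builds the
null by randomly reassigning the A/B labels over the union of observed
positions — positions fixed, identities shuffled — which preserves the
GC's spatial density structure. Two p-values are reported:

* the **primary, calibrated p**: a two-sided permutation p on the median
  A→B distance (add-one estimator, smaller tail doubled). Its type-I
  error sits at the nominal level under label-random maps, which the
  acceptance suite verifies over 500 simulations;
* the **pooled rank-sum p**: observed distances versus all pooled null
  distances, the cumulative-distribution-style comparison often shown in
  figure panels. Pooled null distances are strongly correlated, so this
  p-value overstates precision; it is reported for comparability, not
  inference.

The direction is read off the medians: observed median above the null
median means segregation, below means aggregation, and no call is made
when the calibrated p exceeds the significance level.

# Interface geometry

`delineateInterface()` estimates the DZ region as a raster morphological
closing of the DZ point cloud — an alpha-shape-like concave hull built
from dilation and erosion with a disc of radius `alpha` (default: twice
the median DZ NN spacing). Three robustness measures matter in practice:
the radius is doubled (at most three times) until the largest connected
component holds ≥ 99 % of the closed region, since Poisson gaps fragment
the cloud at the default radius; a coarser closing at 3·alpha seals
cracks and edge pockets (the bridging chords sag far less than the pocket
depth); and enclosed holes are filled. The interface polyline is the part
of the region contour that does not hug the GC polygon (tolerance
2.5·alpha), i.e. the outward-facing edge of the DZ cells; tiny fragments
are dropped.

Signed distances are measured to the interface *polyline* (negative on
the DZ side, sign from region membership) — not to the region edge, which
also runs along the GC outline and would corrupt depth measurements for
cells near the rim. On a half-plane fixture at a realistic GC B-cell
density (0.016 /µm²) the delineated boundary tracks the true midline
within 20 µm.

`densityProfile()` bins the signed distance into half-open `[lo, hi)`
intervals tiling the band (default 100 µm total, i.e. 50 µm inner and
outer layers) and divides per-phenotype counts by bin areas measured on
the raster (pixels inside the GC polygon whose signed distance falls in
the bin; the method is recorded in the output). Range-normalized
distances divide |signed distance| by the compartment's maximum —
per-compartment rather than per-GC, matching the separate DZ and LZ
regressions the analysis feeds — and label cells *close* below 0.4
(configurable).

# Correlation inference

`correlateWithInference()` computes Pearson's r or Kendall's τ with a
two-sided permutation p (shuffling one variable; add-one estimator) and a
percentile bootstrap CI (default b = 1,000 resamples at the 95 % level;
degenerate resamples are redrawn; the interval is widened, if ever
needed, to contain the point estimate). When the full permutation space
fits in the requested budget the space is enumerated and the p-value is
exact. Kendall's permutation p is invariant under monotone rescaling of
either variable, checked in the tests.

# Expression analyses

`simulatePairedROI()` emulates a matched-ROI spatial profiling design:
1,800 genes over 10 DZ/LZ pairs, gene baselines N(7, 1.5²), a shared
per-pair offset (SD 1) that cancels in within-pair differences, planted
log₂ fold changes of ±1 on 150 genes (half up in DZ), and residual SD
0.5.

`moderatedTPairedDE()` reduces the paired design to within-pair DZ−LZ
differences and applies a one-sample t-test with empirical-Bayes variance
shrinkage: the posterior variance is `(d0·s0² + d_g·s_g²)/(d0 + d_g)`
with the prior `(d0, s0²)` estimated by method-of-moments on the log gene
variances (digamma/trigamma moment matching; a trimmed variant is exposed
for heavy-tailed variance fixtures, and `priorDf` can force the
endpoints: 0 recovers the ordinary paired t exactly, `Inf` fully pools).
P-values use `d0 + d_g` degrees of freedom and are BH-adjusted within the
contrast. The test suite cross-checks the statistics against an
independent empirical-Bayes implementation and verifies false-discovery
control, sensitivity and effect-size recovery on the planted design. A
`rank_sum` variant covers the single-cell convention (two-sided rank-sum,
BH, plus an |log-FC| > 0.25 filter).

`scoreSignature()` offers the mean of per-gene z-scores (invariant to
gene-wise affine rescaling) and the plain total of log₂ values.
`tertileStratify()` cuts at the empirical 1/3 and 2/3 quantiles with
boundary ties assigned to the lower stratum. `dzLzGroupAssignment()`
standardizes both signature scores, takes their difference and applies
the tertile rule — top tertile DZ-like, bottom LZ-like — a declared,
reproducible substitute for an unstated clustering rule.

`enrichmentScore()` is the weighted Kolmogorov–Smirnov running sum: hits
advance by |statistic|^weight (normalized), misses decrement uniformly,
and the ES is the signed maximum deviation, in [−1, 1]. Significance
comes from permuting the signature positions over the ranked list
(add-one, two-sided on |ES|), which is calibrated for random signatures.
The leading edge collects the hits up to (or after, for negative ES) the
extremum.

`crossCohortGeneCorrelations()` correlates every DZ-signature gene with a
per-sample mean-z T-cell score inside each cohort, flags significant
negative correlations after BH adjustment within the cohort, counts
flags per gene across cohorts, and selects genes flagged in at least
`min_datasets` cohorts (default 3). Cohorts under 10 samples are excluded
with a warning. Selection is monotone in the threshold. The companion
generator `simulateCohort()` plants a per-sample DZ activity a ~ N(0,1)
loading on the signature genes and a latent T-cell fraction
`plogis(cohort_beta·a + noise)` (default β = −2) loading on a dedicated
T-cell gene block, so recovery and null behaviour are both checkable.

# Pipeline and reproducibility

`runPipeline()` validates a nested configuration (unknown keys are
rejected), derives every stage seed from the global seed, chains
simulation → chrometrics → classification → spatial statistics →
signatures, writes each result as CSV/TSV/JSON under the output
directory, and ends with a manifest carrying the config hash, seeds,
package version and per-file checksums. Stage subsets reuse upstream
outputs already on disk. Re-running the bundled demo configuration
produces byte-identical tables, which both the test suite and
`scripts/acceptance.R` verify. The chrometrics stage segments the
rendered image (Otsu threshold, hole filling, optional watershed) and
joins segmented nuclei to planted cells by centroid proximity; the
classification stage trains on the resulting labelled features.

A thin command-line wrapper (`inst/scripts/gcniche`) exposes `run`,
`simulate`, `classify` and `spatial` subcommands over the same functions
with conventional exit codes (0 success, 2 validation error, 1 runtime
failure); the R functions remain the primary interface.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at sizes chosen to make
Monte Carlo error small relative to the properties being checked: 500
label-random maps of 300 cells (200 permutations each) for type-I
calibration; 100 thinned maps for segregation power; 400 nuclei for the
planted-gap classifier and 8 × 500 for the null band (averaging
independent renders keeps the chance-band check inside ±1 SE); 20
replicates of the 1,800-gene, 10-pair paired design; 200 replicates for
bootstrap-coverage estimation; 8 cohorts of 300 samples for the
cross-cohort recovery. Quantile convention is type-7 linear interpolation
throughout; rank ties use midranks; bins are half-open `[lo, hi)`; pixel
coordinates are 0-based with physical units attached via the pixel size;
distances are in micrometers.

# Known limitations

* The nuclei renderer draws disc-shaped, non-touching nuclei with
  idealized two-level chromatin texture; morphology features are
  therefore uninformative in synthetic fixtures, and classifier
  accuracies are optimistic relative to stained tissue.
* The interface method is raster-based; its boundary fidelity degrades
  below roughly three times the point spacing, and very sparse DZ clouds
  fall back to progressively coarser closings.
* The pooled rank-sum p of the randomization test is reported for
  comparability with CDF-style figure panels but is not calibrated; use
  the primary permutation p for inference.
* Cross-cohort analysis treats the T-cell signature composition as given
  input; no deconvolution is performed.
* No survival analysis, batch correction, or cross-platform
  harmonization is included.
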