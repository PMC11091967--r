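---
title: "ProbeQuant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProbeQuant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProbeQuant)
```

ProbeQuant implements the computational side of a fluorescent
receptor-probe development workflow built around calcium-sensing receptor
(CaSR) ligands: which chemical scaffold tolerates structural modification,
whether a conjugated probe labels receptor-positive cells specifically, and
what its photophysical and pharmacological constants are. This vignette
explains the models behind each stage, the tunable parameters, what the
synthetic-data generators do and do not emulate, and the design decisions
that were genuinely open.

## Scaffold tolerance from substructure fingerprints

Compounds are represented as 881-bit binary substructure fingerprints (the
PubChem 2D convention), grouped into assays by the bioassay that measured
their half-maximal activity concentration (AC50, in uM). Assays with fewer
than 20 compounds are excluded (`minCompounds`), mirroring the usual
inclusion rule for public activity data.

Structural similarity is the Tanimoto index on bit sets,
$T(a,b) = |a \wedge b| / |a \vee b|$. The chemical space is embedded with
PCA (`embedFingerprints()`, 20 latent dimensions by default; downstream
steps use the first 10). Component signs are fixed by forcing the
largest-magnitude loading positive, so embeddings are reproducible across
platforms. A compound-compound Pearson correlation matrix over the retained
scores (`compoundCorrelation()`) gives the heatmap-style view of the space.

Clustering is plain k-means. The cluster count is chosen by knee detection
on the inertia curve (`selectKneedle()`): both axes are normalized to
$[0,1]$ and the knee maximizes $D(k) = (1-x_n) - y_n$, the kneedle
criterion in its decreasing-convex orientation. An exactly linear curve has
no knee and is an error; callers may fall back to the maximum-sensitivity
k. Two details matter in practice:

* **Restarts.** `scaffoldAnalysis()` uses 50 k-means restarts per k
  (`nInit`). With 10 restarts a single misconverged fit at larger k (we
  observed inertia 3783 where the clean optimum was 96) flattens one drop
  of the curve and fakes a knee one position early. Fifty restarts keep the
  sweep clean up to k = 12 at negligible cost on these problem sizes.
* **What is clustered.** The default clusters the rows of the
  compound-compound correlation matrix, the reading in which the
  correlation map itself is the clustering substrate; `clusterOn =
  "scores"` clusters the 10-dimensional PC scores directly, the more
  conventional choice. Both are exposed because the two readings are
  genuinely defensible; cluster-number recovery on planted libraries is
  equally good either way.

Scaffold tolerance is the quadrant statistic (`quadrantScore()`): within an
assay, every compound is placed in the plane of (Tanimoto similarity to the
assay's most potent compound) x (AC50), cut at `potencyCutoff` (default
0.1 uM) and `similarityCutoff`. The tolerance score is
$q_3/(q_1+q_2)$ - potent-but-dissimilar compounds over all non-potent ones.
A positive score says the scaffold keeps potency under structural change,
which is what one wants before attaching a fluorophore. The similarity
boundary is not a standard constant; we default to 0.8 and note that
positivity of a genuinely tolerant assay only requires $q_3 \ge 1$, which
is robust across cutoffs 0.5-0.9 (this is exercised in the tests). Ties for
the most potent compound are broken toward the smallest compound id and
recorded. When an assay has no non-potent compounds at all, the score is
flagged infinite and sorts first in `rankAssays()`.

## Imaging: labeling specificity by pixel skewness

Receptor-bound probe accumulates in membrane puncta; free or nonspecific
probe is diffuse. On a per-cell pixel-intensity distribution this is a
difference in asymmetry, so the readout is the third standardized moment
(bias-uncorrected Fisher-Pearson $g_1$; with thousands of pixels per cell
the bias-corrected variants are numerically indistinguishable).

The background of each image is the mean of pixels that are outside every
cell label *and* below the triangle threshold of the probe histogram
(`estimateBackground()`). The triangle threshold (`triangleThreshold()`)
draws a line from the histogram peak to the far end of its longer tail and
cuts at the bin of maximal perpendicular distance; we use 256 equal-width
bins over the image range (the 8-bit convention) on the raw, not
log-transformed, histogram. The method characteristically lands at the
foot of the dominant peak, which is the desired behavior for separating a
dark background mode from label signal. Per-cell means are divided by this
background (`mean_normalized`), which makes them invariant to detector
gain.

Group differences use the two-sided Mann-Whitney rank-sum test with
Bonferroni adjustment over the planned comparisons (`compareGroups()`), and
the effect size is the fold change of group medians. Cells under
`minPixels` (default 50) are segmentation slivers and are dropped with a
logged count; zero-variance cells have undefined skewness and are flagged
`NA`.

Masks are expected from an external segmenter (in the original workflow a
neural network; the package consumes its label TIFFs). `fallbackSegment()`
- triangle threshold plus connected components with an area filter -
exists so synthetic fixtures never need that dependency; it may merge
touching cells and says so via the `possiblyMerged` attribute.

## Photophysics

* **Extinction coefficient**: ordinary least squares of absorbance on
  concentration x path length, forced through the origin because
  Beer-Lambert has no intercept; `intercept = TRUE` is available to
  diagnose instrument offsets.
* **Relative quantum yield**:
  $\Phi_s = \Phi_r (m_s/m_r)(n_s/n_r)^2$ with $m$ the
  fluorescence-vs-absorbance slopes and $n$ the solvent refractive indices.
  The index ratio is squared, per the standard relative method; when sample
  and reference share a solvent (the common case here, 94% ethanol,
  $n = 1.3617$) the factor is exactly 1, so the exponent is not observable
  in-sample. The default reference is Rhodamine B, $\Phi_r = 0.68$. Yields
  above 1 are physically suspect and warned about. Peak-intensity slopes
  are used rather than integrated emission (config-switchable in how the
  inputs are prepared).
* **Lifetime**: single-exponential decay with a floating baseline, fitted
  from the trace peak onward by Levenberg-Marquardt, with start values
  from a log-linear fit of the tail. Multi-exponential models are out of
  scope; traces averaged over acquisition cycles are fitted once.

## Dose-response

All curves go through a four-parameter logistic on $\log_{10}$
concentration (`fitHill()`): bottom, top, half-maximal concentration and a
Hill coefficient bounded to $[0.2, 10]$. Five EC50 starts spanning the
tested range guard against local minima. The `converged` flag is honest: it
requires a finite standard error, a fitted span clearly above residual
noise, and an inflection inside (a 2-decade margin of) the tested range.
Asymptotic standard errors come from the Jacobian; EC50's SE is mapped to
the natural scale by the delta method.

Calcium-transient responses are summarized as
$\mathrm{d}F/F_0 = (\max_{1..200} F - F_0)/F_0$ with $F_0$ the mean of the
first `baselineWindow` frames (default 10; the peak window of 200 frames is
the instrument convention). Receptor-specific binding divides
receptor-positive by receptor-negative fluorescence per concentration
(`casrSpecificRatio()`); the dissociation constant comes from the one-site
form $r(c) = 1 + A\,c/(K_d + c)$ (`fitSaturationKd()`). When the amplitude
is unidentifiable or $SE(K_d) > K_d$, the result is flagged rather than
reported as a constant. `washoutShift()` tabulates EC50 fold shifts against
the no-wash condition.

## What the generators emulate

The synthetic generators define the study conditions under which the
pipeline is validated; every downstream claim in the test suite is a
recovery statement about their planted truth.

* `simulateAssayLibrary()`: `nClustersTrue` random 881-bit prototypes at
  15% bit density; compounds are per-bit noisy copies (flip probability
  0.01) and each assay draws from a single scaffold cluster, the way one
  bioassay usually covers one chemotype series. AC50s are log-normal
  (sdlog 0.4) around cluster medians drawn log-uniformly in [0.01, 10] uM.
  The flip rate is set by Tanimoto geometry: at 0.01 same-cluster pairs sit
  near 0.88 similarity and cross-cluster pairs near 0.1, so planted
  structure survives any similarity cutoff in 0.5-0.9; at 0.05 same-cluster
  similarity collapses to about 0.6 and no quadrant boundary can separate
  the classes. The tolerant assay receives 10% planted compounds from
  another cluster, potent (0.02-0.09 uM) and forced below 0.4 similarity to
  the assay's reference; non-tolerant assays are guaranteed clean - a
  noise-generated structural outlier that happens to be potent has its
  AC50 redrawn above the cutoff, making the planted design exact by
  construction. Cluster-number experiments use `nAssays = 2 * kTrue`
  (balanced clusters, 20 compounds per assay); with unbalanced planted
  clusters the knee of the inertia curve genuinely sits below the planted
  k, which is a property of the data, not of the detector.
* `simulateImagePair()`: single-plane 16-bit-range images, disk-shaped
  cells (radius 24 px) placed without overlap, membrane puncta as isotropic
  Gaussians of sigma 2 px centred on the cell boundary, diffuse in-cell
  signal with multiplicative log-normal texture (sdlog 0.15) - real diffuse
  labeling is mildly right-skewed, and without that texture the
  receptor-negative skewness median sits at zero and fold changes are
  undefined. Gaussian read noise (sd 20) on top. Not emulated: focus
  drift, uneven illumination, debris, touching cells, 3D structure - so a
  passing suite says the statistics behave, not that segmentation-hard
  images are handled.
* `simulatePhotophysics()`: Beer-Lambert absorbance over 150-1350 nM at
  1 cm path, slope-encoded quantum-yield series, single-exponential decay
  (peak 1e4 counts, baseline 10) with optional Poisson counting noise.
* `simulateDoseResponse()` / `simulateSaturationCurve()`: Hill and one-site
  curves over 8 half-log concentrations around the planted constant with
  multiplicative log-normal noise (CV 5% and 10% respectively);
  triplicate wells per concentration, matching plate-reader practice of
  averaging triplicates - with single wells at 10% noise the Kd of a
  one-site fit on 8 points is simply not estimable to useful precision.

Problem sizes used by the validation suite and the acceptance script (100
libraries for ranking, 50 per planted k for cluster-number recovery, 3
image pairs per group, 100 seeds per curve-fit statistic) were chosen so
the whole validation runs in minutes on one core while keeping the
binomial uncertainty of the reported rates a few percent.

## Numerical choices and degenerate inputs

* Tanimoto of two all-zero fingerprints is an error (undefined), and an
  all-zero reference compound is rejected; an all-zero compound against a
  nonzero reference is similarity 0.
* PCA on an all-constant matrix errors naming the degenerate columns;
  constant *individual* columns (bits never set) are fine.
* A flat histogram has no triangle geometry: midpoint with a warning. A
  single-bin histogram is an error.
* k-means at k = n returns the trivial zero-inertia partition directly
  (stats::kmeans refuses it).
* Flat saturation curves return `flagged = TRUE` with `NA` Kd instead of a
  number.
* All generator randomness flows from one explicit seed per call through a
  local RNG scope, so library calls never disturb the session RNG and
  per-seed output is bit-identical; `runDemo()` reports are byte-identical
  per seed.

## Known limitations

* Fingerprints are abstract bit vectors; no chemistry (valence, rings,
  synthesizability) is simulated, and no fingerprint computation from
  structures is provided - fingerprints are inputs.
* The fallback segmenter is for fixtures, not for real micrographs.
* Lifetimes are single-exponential only; quantum yields assume the dilute
  (linear absorbance-fluorescence) regime.
* `fetchPubChemAssays()` needs network access and is deliberately isolated
  from the analysis modules, which are pure and offline.
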