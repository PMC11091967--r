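# ProbeQuant

Computational toolkit for developing fluorescent small-molecule probes
against cell-surface receptors, modeled on a calcium-sensing receptor
(CaSR) probe workflow. It answers, with reusable and tested code, the four
quantitative questions of that workflow:

1. **Which chemical scaffold tolerates modification?** From 881-bit
   substructure fingerprints and AC50 tables, per-assay *quadrant tolerance
   scores*: each compound is placed in the plane of (Tanimoto similarity to
   the assay's most potent compound) × (AC50), and the score is
   `q3 / (q1 + q2)` — potent-but-dissimilar compounds over non-potent ones.
   A positive score flags a scaffold that keeps potency under structural
   change. The chemical space itself is mapped with PCA (20 latent
   dimensions), a compound–compound correlation matrix over the first 10,
   and k-means with the cluster number chosen at the kneedle knee of the
   inertia curve.
2. **Does the probe label receptor-positive cells specifically?** Per-cell
   skewness of the probe-channel pixel distribution (membrane puncta are
   right-skewed; diffuse labeling is not), with image background estimated
   from non-cell pixels below the triangle threshold, and Mann–Whitney
   comparisons with Bonferroni correction.
3. **What are its photophysical constants?** Extinction coefficient
   (Beer–Lambert regression through the origin), relative quantum yield
   `Φs = Φr·(ms/mr)·(ns/nr)²` against a reference standard, and
   single-exponential fluorescence lifetime.
4. **What are its pharmacological constants?** Four-parameter logistic
   (Hill) fits for EC50/IC50, dF/F0 extraction from calcium transients,
   receptor-positive/negative fluorescence ratios and one-site saturation
   Kd, and washout EC50 shift tables.

Every input class has a seeded synthetic generator with known ground truth
(`simulateAssayLibrary()`, `simulateImagePair()`, `simulatePhotophysics()`,
`simulateDoseResponse()`, `simulateSaturationCurve()`), so the whole
pipeline is testable offline; `fetchPubChemAssays()` can optionally pull
real bioassay tables when a network is available.

## Worked example

```r
library(ProbeQuant)

# a library of 10 assays, one of which (assay 2) is planted tolerant
lib <- simulateAssayLibrary(tolerantAssay = 2, seed = 1)
res <- scaffoldAnalysis(lib$assays, kRange = 2:12, seed = 1)
res$ranking
#>    aid reference_cid q1 q2 q3 q4 score infinite rank
#> 1  A02       A02-001  0  0  4 35   Inf     TRUE    1
#> 2  A01       A01-024  0 39  0  0     0    FALSE    2
#> 3  A03       A03-020  0 39  0  0     0    FALSE    3
#> ...
res$k
#> [1] 5
```

The planted tolerant assay is ranked first: it is the only one with
potent-but-dissimilar compounds (`q3 = 4`; here it has no non-potent
compounds at all, so its score is flagged infinite), and the kneedle knee
of the k-means inertia curve recovers the five planted scaffold clusters.

```r
pair <- simulateImagePair(imageSpec(seed = 1))
bg <- estimateBackground(pair$pos$probe, pair$pos$mask)
bg
#> [1] 201.7   # planted background: 200
head(measureCells(pair$pos$probe, pair$pos$mask, bg), 3)
#>   cell_id n_pixels mean_raw mean_normalized skewness
#> 1       1     1804   660.3            3.27     3.96
#> 2       2     1809   662.9            3.29     3.12
#> 3       3     1810   664.5            3.29     4.21
```

Receptor-positive cells show per-cell skewness near 4 (membrane puncta);
the matched receptor-negative images give ~0.4, a ~10-fold separation that
the Mann–Whitney comparison calls at p « 0.001.

`runDemo(seed = 1, outDir = "demo")` runs all four stages end to end and
writes a JSON report that is byte-identical per seed; a thin shell wrapper
lives at `inst/scripts/probequant-demo.R`.

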