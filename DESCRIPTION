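Package: ProbeQuant
Title: Scaffold Tolerance, Labeling Specificity and Photophysics for Fluorescent Receptor Probes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational toolkit for the development of fluorescent
    small-molecule receptor probes, built around the calcium-sensing
    receptor (CaSR) ligand space. Scores the tolerance of chemical
    scaffolds to structural modification from 881-bit substructure
    fingerprints and AC50 tables (Tanimoto similarity, PCA embedding,
    k-means with kneedle cluster-number selection, quadrant tolerance
    statistic); quantifies receptor-specific membrane labeling in
    two-channel microscopy images (triangle-threshold background
    estimation, per-cell pixel-intensity skewness, rank-based group
    comparisons); fits photophysical constants (extinction coefficient,
    relative quantum yield, fluorescence lifetime) and pharmacological
    curves (four-parameter logistic EC50/IC50, one-site Kd from
    receptor-positive/negative fluorescence ratios). Includes seeded
    synthetic-data generators with known ground truth for every input
    class, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    graphics,
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
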