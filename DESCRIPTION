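Package: AAoTraits
Title: Ascending Aortic Size and Distensibility from Cine CMR, with
    Instrument Discovery and Mendelian Randomization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for ascending aortic (AAo)
    phenotyping from cine cardiovascular magnetic resonance segmentation
    masks and for downstream genetic epidemiology. Provides a synthetic
    cine and summary-statistic generator with known ground truth; a
    classical baseline lumen segmenter; contour, bounding-ellipse and
    metric feature extraction; quality control built on relative
    roundness, area bounds and the Immerkaer inter-pixel noise estimate;
    per-participant phenotype derivation (maximum and minimum
    cross-sectional area, distensibility, body-surface-area indexing,
    rank-based inverse normal transformation, stratified reference
    tables); agreement metrics (Dice, two-way random-effects ICC);
    desk-scale association testing with greedy linkage-disequilibrium
    clumping and locus definition; and a two-sample Mendelian
    randomization engine with harmonization, instrument-strength and
    Steiger filtering, inverse-variance-weighted random-effects and
    MR-Egger estimation under the Ruecker model-selection framework, and
    weighted-median and weighted-mode sensitivity estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CardiacImaging, QualityControl, GenomeWideAssociation
Collate: 
    'AAoTraits-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'features.R'
    'gwas.R'
    'io.R'
    'mr-estimators.R'
    'mr-harmonize.R'
    'phenotypes.R'
    'pipeline.R'
    'qc.R'
    'segmentation.R'
    'synthetic-cine.R'
    'synthetic-genetics.R'
    'validation.R'
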