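---
title: "AAoTraits: models, quality control and Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AAoTraits: models, quality control and Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(AAoTraits)
```

# Overview

AAoTraits implements an end-to-end pipeline for ascending aortic (AAo)
phenotyping from cine CMR segmentation masks and for the genetic analyses
that such phenotypes feed: per-frame geometric feature extraction, a
quality-control (QC) cascade, per-participant phenotype derivation,
desk-scale instrument discovery, and a two-sample Mendelian randomization
(MR) engine with a full sensitivity tier. A synthetic-data module generates
cine studies and GWAS summary statistics with known generative truth, so
every stage has an oracle.

This vignette is the package's own account of the models it implements, the
design decisions taken where choices were genuinely open, and what the
synthetic tests do and do not establish about real data.

# Phenotype model

Per retained frame the lumen mask yields a contour area; per participant

* `AAomax` / `AAomin` are the maximum / minimum of the per-frame areas —
  the systolic and diastolic extremes of the cycle. We use extremes rather
  than phase averages because distensibility is defined through the
  *relative enlargement* between diastole and systole; any averaging would
  shrink the numerator.
* distensibility is `(AAomax − AAomin) / (AAomin · PP)` with
  `PP = SBP − DBP` (mmHg), reported in 10⁻³ mmHg⁻¹. It is a ratio of areas
  scaled by pressure, hence invariant to area units; `deriveAAoPhenotypes()`
  returns it missing (with a reason) when PP ≤ 0, when blood pressure is
  absent, or when fewer than two frames survive QC.
* areas and diameters are indexed to body surface area. BSA uses Du Bois
  (`0.007184·w^0.425·h^0.725`) by default — the long-standing convention of
  the indexing literature — with Mosteller selectable.

For association testing, phenotypes are inverse-rank-normalized:
`Φ⁻¹((rank − 0.5)/n)` with average ranks for ties. The half offset is the
simplest symmetric choice; Blom's 3/8 offset is available behind a flag and
differs negligibly at cohort sizes of interest.

# Geometric features and their conventions

* **Contour**: the 8-connected outer border polygon of the (single) mask
  component, coordinates (row, col), 0-based, pixel centres at integer
  positions. Area is the shoelace formula on that polygon; perimeter is its
  arc length with diagonal steps weighted √2. These are the conventions of
  the standard contour-moment implementations, and they are what the
  roundness ratio `4π·area/perimeter²` implicitly assumes. A consequence
  worth knowing: the border polygon runs through the centres of border
  pixels, about half a pixel inside the true boundary, so the shoelace area
  of a disk of radius r px tracks `π(r − ½)²` rather than `πr²` (≈ −4% at
  r = 25, the scale of an aorta at 0.6 mm/px). The raw pixel count, which
  is nearly unbiased, is carried alongside as a diagnostic
  (`pixelCountAreaCm2`). Ratio phenotypes inherit a small positive bias
  from the denominator; on a 300-participant synthetic cohort the
  regression of estimated on true distensibility has slope ≈ 1.03 at
  0.3 mm/px (within the package's 0.95–1.05 recovery property), and the
  canonical-participant recovery test runs at 0.25 mm/px where the bias is
  well under 2%.
* **Smallest bounding ellipse**: read as the minimum-volume enclosing
  ellipse (MVEE) of the contour vertices, computed by Khachiyan's
  barycentric coordinate ascent (with drop steps) to an optimality
  tolerance of 1e-7 on the convex hull of the vertices; the returned
  ellipse is inflated by the worst vertex's quadratic form so containment
  holds to 1e-6 (scaled). Whether a "smallest bounding ellipse" means an
  enclosing ellipse or a least-squares fit is ambiguous; both are
  implemented (`method = "mvee"` default, `method = "lsq"` a direct
  algebraic conic fit), and for near-elliptical lumina they agree closely.
  Degenerate (collinear) vertex sets raise an error. Rasterized perfect
  ellipses are the slow case for the iteration (many near-active hull
  points); `extractStudyFeatures(ellipse = FALSE)` skips the fit when only
  areas are needed.
* **Metric conversion**: area uses the exact spacing product
  `area_px·sx·sy/100` (cm²); lengths use the common spacing, or the mean
  spacing with a warning when anisotropy exceeds 1%, since no single length
  scale then exists. The AAo diameter is the mean of the two converted
  ellipse axis lengths.

# Quality control

Frame rules, applied in order (first failure wins): empty mask, roundness
< 0.85, area < 3 cm², area > 20 cm². Roundness is computed in pixel space
before metric conversion, immediately after extraction. Participant rules:

* excluded from **all traits** when more than 25% of frames fail frame QC
  (strictly more: 25/100 passes, 26/100 fails), when no frame is retained,
  or when the mean |area(i+1) − area(i)| over consecutive *retained* frames
  exceeds 0.3 cm² (frames dropped by frame QC are skipped, and the
  difference is taken between the retained neighbours — the treatment of
  gaps is our choice);
* excluded from **AAomax and AAodist** — but not AAomin — when any frame's
  noise estimate σₙ exceeds 4.1. Flow-void artefacts are systolic, so the
  diastolic minimum is unaffected; the synthetic generator injects
  artefacts only into systolic-window frames for the same reason. The 25%
  budget counts frame-QC failures only, not σₙ-flagged frames, which act at
  the participant level;
* excluded from AAomax/AAomin when BSA inputs are missing, and from
  AAodist when either blood pressure is missing.

The σₙ threshold of 4.1 presumes a 0–255-like brightness scale (the
generator emits one); because acquisition intensity scales vary, the
threshold is a `qcThresholds()` parameter rather than a constant.
The Immerkær estimator itself is exact for i.i.d. Gaussian noise (the
checkerboard closed form `sqrt(π/2)·8/6` and a 5%-accurate recovery of
injected σ = 5 are test oracles) and is blind to constant offsets and
linear ramps because the kernel's rows and columns sum to zero; it is not
blind to sharp edges, which contribute a small positive term — one more
reason the crop is centred on the vessel rather than taken over the full
frame.

Exclusion is monotone: tightening any threshold can only shrink the
included set (property-tested).

# The synthetic generator

The generator is the package's study-condition definition, not a tuning
knob. Defaults emulate a population with diastolic area ~7.2 cm², systolic
~8.1 cm² (drawn uniformly, systole resampled to dominate diastole), SBP
~N(133.6, 17.8), DBP ~N(78.9, 8.5) (PP ≈ 54.7 mmHg), height/weight giving
BSA ≈ 1.9 m², ages 45–80, 100 frames per cycle, 192×192 px at 0.6 mm/px.
The lumen is a near-circular ellipse (aspect 0.94–1; the AAo cross-section
is close to circular in a perpendicular acquisition) whose area follows a
raised-cosine pulse occupying the first 40% of the cycle — smooth, single
systolic peak, well-separated extremes. Brightness: lumen ~200, background
~60 with low-frequency sinusoidal texture (deliberately smooth so it cannot
excite the noise kernel), Gaussian noise σ = 2.5, and a logistic edge
profile ~0.5 px wide so the threshold segmenter faces a boundary of
realistic softness. Flow-void artefacts add zero-mean uniform noise of
amplitude 40 inside the lumen of systolic-window frames, which drives σₙ
from ≈2.6 to ≈9–10, comfortably across the 4.1 threshold — on artefact
frames only. One global seed plus a per-participant hash gives
reproducible, order-independent generation.

What the generator does *not* emulate: partial-volume effects, coil
inhomogeneity, motion between frames, non-elliptical lumina,
through-plane angulation, and any real scanner noise spectrum. Passing
tests therefore establish internal consistency of the pipeline (the
segmenter, features, QC rules and phenotype algebra agree with the
generative truth), not segmentation performance on clinical images.

The summary-statistic simulator draws per-variant exposure effects from a
half-normal (effect alleles oriented to increase the exposure, as reported
GWAS lead variants are) *conditional on detectability*
(|βX| > 5.45·SE, the genome-wide threshold): instruments are by definition
variants that passed such a screen, and including undetectable effects
would make the estimated allele orientation random for near-zero effects —
an artefact no real instrument set has. Outcome effects are
`θ·βX + α + noise`, with the pleiotropy term α identically zero under
`"none"` (so the InSIDE assumption holds by construction), N(0, sd) under
`"balanced"`, N(mean, sd) under `"directional"`, and correlated with
instrument strength under `"inside_violating"`. The default outcome sample
size (20 000) is an *effective* sample size, the `4p(1−p)N` a low-prevalence
binary outcome yields in a large cohort; pairing tight outcome SEs (e.g.
N = 300 000 quantitative-scale) with 30 000-sample exposures would make
regression-dilution bias dominate the sampling error, which is not the
regime instrument-based inference is used in.

# Mendelian randomization

* **Harmonization**: outcome tables are aligned to the exposure's effect
  allele; swapped alleles flip the outcome beta, strand flips are resolved
  by complementing. Palindromic variants are resolved by allele frequency
  and removed when MAF > 0.42 (or when frequency is missing).
* **Instrument strength**: `R² = 2·maf(1−maf)·βX²` for the unit-variance
  transformed exposure; for binary outcomes, a latent-logistic
  approximation `βY²v/(βY²v + π²/3)`. `F = R²(n−2)/(1−R²)`; F ≤ 10 flags
  (not removes) weak instruments. The exact published R² formulas for the
  binary case are not uniquely pinned down; the implemented approximation
  is recorded in the function metadata.
* **Steiger filtering** removes a variant only when it explains more
  outcome than exposure variance *and* a two-sided Fisher-z comparison of
  the implied correlations is significant at 0.05 (two-sided because the
  direction of the violation is what is being tested; a one-sided variant
  would only be more permissive).
* **IVW-RE**: zero-intercept weighted regression with weights 1/seY²;
  multiplicative random effects scale the SE by `sqrt(max(1, Q/(k−1)))` —
  never deflating it — matching the convention of standard two-sample MR
  tooling. With k = 1 it reduces exactly to the Wald ratio.
* **MR-Egger** frees the intercept; variants are first oriented so every
  βX ≥ 0 because Egger is not orientation-invariant. `I²GX`, the
  precision-weighted dispersion of the exposure effects, qualifies the fit:
  under exposure measurement error the slope attenuates and the intercept
  test can fire without true directional pleiotropy. This is visible in the
  package's own simulations: with strong instruments (the detectability
  screen) the intercept recovers an injected α = 0.03 within Monte-Carlo
  error at θ = 0, while at non-zero θ a small leak through the diluted
  slope remains — the reason the recovery test isolates the intercept
  channel.
* **Rücker decision**: IVW-RE is the main model; the analysis switches to
  MR-Egger only when the heterogeneity drop Q − Q′ exceeds the χ²₁ 0.05
  critical value *and* the intercept differs from zero at 0.05. Both fits
  are always reported.
* **Weighted median / mode**: inverse-variance-weighted median with linear
  interpolation at cumulative weight ½; mode of the weighted
  normal-kernel-smoothed ratio density (bandwidth = factor × modified
  Silverman rule `0.9·min(sd, mad)·k^{−1/5}`). Standard errors come from a
  parametric bootstrap (1000 replicates, fixed seed) so reports are
  deterministic.
* **Report**: odds ratios are exponentiated estimates; the main model's p
  is tiered at the Bonferroni level 0.05/10 = 0.005 (significant) and 0.05
  (suggestive). CIs are normal-theory on the log scale.

# Instrument discovery (desk scale)

Association testing is OLS with covariates on unrelated synthetic
individuals — mixed-model machinery would model relatedness that the
generator does not create. Variants are pre-filtered at MAF ≥ 0.5% and
INFO ≥ 0.3 (when present). Greedy clumping iterates candidates by ascending
p (ties by position, so outputs are deterministic), removing everything
with r² ≥ 0.005 within ±5 Mb of each selected lead; r² is the squared
Pearson correlation of dosages. Leads at p < 5×10⁻⁸ are marked genome-wide
significant. Loci are ±1 Mb intervals around leads, merged across traits on
overlap with the lowest-p lead retained. λ is the median association χ²
over 0.4549.

# Numerical choices and degenerate inputs

* Khachiyan tolerance 1e-7 (optimality gap), hull reduction first,
  post-hoc containment inflation; collinear input errors out.
* Empty or single-pixel masks signal "empty" rather than erroring; a
  constant image segments to an empty mask; border-touching components are
  flagged but measured.
* Dice of two empty masks is defined as 1 and flagged (`bothEmpty`), so
  agreement-on-absence can be excluded by callers.
* ICC is ICC(2,1) — two-way random effects, single measure, absolute
  agreement — the standard reading for method comparison; the consistency
  form is available behind a flag. The CI uses the F-based construction
  with Satterthwaite df. Zero total variance errors out.
* All-equal input to the inverse-normal transform errors out (ranks carry
  no information); NAs pass through without consuming ranks.
* The bootstrap, the genotype generator, the cine generator and the
  pipeline all restore the caller's RNG state.

# Problem sizes in the test-suite

The suite exercises the full pipeline at sizes chosen to keep the oracles
sharp: 200-frame fixtures for segmentation Dice, a 100-participant cohort
for the ICC agreement property, 300 participants at 0.3 mm/px for
distensibility-slope recovery, 500 participants (64 px frames) for the
Monte-Carlo check of the generator's distensibility distribution, 200
replicates for the MR recovery and Egger-intercept checks, and randomized
≤ 12-variant instances against a step-by-step enumeration oracle for
clumping. `scripts/acceptance.R` re-runs the headline quantities at these
sizes in well under a minute.

# Known limitations

* The baseline segmenter is a global threshold with component selection —
  a stand-in adequate for bright-lumen synthetic frames, not a clinical
  segmenter; external model output can be supplied as mask directories.
* The border-polygon area convention carries the half-pixel bias discussed
  above; at clinical pixel spacings this is a few percent on area and
  partially cancels in the distensibility ratio.
* Binary-outcome R² for Steiger uses a latent-scale approximation.
* The association stage is plain OLS; population structure, relatedness
  and imputation uncertainty are out of scope.
* The pipeline's MR stage consumes simulated summary statistics; wiring it
  to the desk-scale association output would require cohort sizes far
  beyond what a synthetic demo runs.
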