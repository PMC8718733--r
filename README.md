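# AAoTraits

Phenotyping of the ascending aorta (AAo) from cine cardiovascular magnetic
resonance (CMR) segmentation masks, and downstream genetic epidemiology —
built as one testable pipeline with a synthetic-data generator providing
ground truth at every stage.

## What it does, and for whom

Cardiovascular imaging groups derive two families of AAo traits from a cine
loop acquired over one cardiac cycle at the level of the pulmonary trunk:

* **Size** — the maximum (systolic) and minimum (diastolic) cross-sectional
  lumen area, `AAomax` and `AAomin` (cm², also indexed to body surface
  area), and the matching diameters from the smallest bounding ellipse.
* **Function** — distensibility, the relative systolic enlargement per unit
  pulse pressure:

  ```
  AAodist = (AAomax − AAomin) / (AAomin · PP),   PP = SBP − DBP
  ```

  reported in 10⁻³ mmHg⁻¹.

Automated segmentation at biobank scale needs automated quality control.
Per frame, the package computes the relative roundness of the lumen contour
(`Rr = 4π·area / perimeter²`, 1 for a circle), bounds on plausible lumen
area (3–20 cm²), and the Immerkær fast noise estimate

```
σₙ = sqrt(π/2) · 1/(6(W−2)(H−2)) · Σ |I ∗ N|,   N = [1 −2 1; −2 4 −2; 1 −2 1]
```

on a centred 80×80 crop, which flags flow-void artefacts (high-frequency
brightness fluctuation around the vessel during systole). Participant-level
rules (excess excluded frames, unstable frame-to-frame areas, σₙ > 4.1,
missing BSA or blood pressure) decide per-trait inclusion.

Downstream, the package provides desk-scale instrument discovery
(covariate-adjusted association, greedy LD clumping at r² < 0.005 within
±5 Mb, ±1 Mb locus definition, genomic-inflation λ) and a two-sample
Mendelian randomization engine: harmonization with the palindromic
MAF > 0.42 rule, per-variant R²/F instrument strength, Steiger filtering,
IVW with multiplicative random effects, MR-Egger under the Rücker
model-selection framework (switch only when the Q − Q′ drop **and** the
Egger intercept are both significant at 0.05), and weighted-median /
weighted-mode sensitivity estimators, with Bonferroni tiering
(0.05/10 = 0.005 significant, < 0.05 suggestive).

Everything runs on synthetic data with known generative truth — cine loops
with a raised-cosine systolic pulse, configurable flow-void artefacts, and
GWAS summary statistics with configurable causal effect and pleiotropy — so
every stage is testable without any data download.

## Worked example

```r
library(AAoTraits)

cfg   <- cohortConfig(nParticipants = 1, nFrames = 20,
                      artefactProbability = 0, seed = 42)
study <- generateCineStudy(cfg, "P001")
study
#> CineStudy 'P001': 20 frames of 192x192 px, spacing 0.6 x 0.6 mm [with ground truth]

feats <- extractStudyFeatures(study)   # baseline segmentation per frame
head(round(feats[, c("frame","areaCm2","diameterMm","roundness","noiseSigma")], 3), 3)
#>   frame areaCm2 diameterMm roundness noiseSigma
#> 1     1   7.481     31.393     0.895      2.517
#> 2     2   7.598     31.736     0.902      2.578
#> 3     3   8.006     32.488     0.897      2.602

report <- participantQC(feats, covariates(study))
report
#> Participant QC: 0 of 20 frames excluded; mean |dArea| = 0.114 cm^2; max sigma_n = 2.65
#>   included for: AAomax, AAomin, AAodist

cv   <- covariates(study)
phen <- deriveAAoPhenotypes(feats[report$retainedFrames, ], cv$sbp, cv$dbp,
                            computeBSA(cv$height, cv$weight))
round(phen[, c("aaoMaxCm2","aaoMinCm2","aaoMaxIdx","distensibility","pp")], 2)
#>   aaoMaxCm2 aaoMinCm2 aaoMaxIdx distensibility    pp
#> 1      8.51      7.46      4.38           4.37 32.36
groundTruth(study)$distensibility
#> [1] 4.315036
```

The per-frame areas track the generative schedule, every frame passes QC
(roundness ≈ 0.9, σₙ ≈ 2.6 ≪ 4.1), and the estimated distensibility
(4.37 × 10⁻³ mmHg⁻¹) recovers the generative truth (4.32) to ~1%; this
participant's low pulse pressure (32 mmHg) puts it in the upper
distensibility range.

Two-sample MR on simulated summary statistics with a causal odds ratio of
1.5 on 60 instruments:

```r
ss   <- generateMRSummaryStats(mrSimConfig(60, theta = log(1.5), seed = 7))
hset <- harmonizeInstruments(ss$exposure, ss$outcome,
                             exposureName = "AAomax", outcomeName = "aneurysm")
an   <- mrAnalyze(hset, seed = 7)
an$ivw
#> IVW-RE: estimate 0.3881 (SE 0.0231), 95% CI [0.3428, 0.4334], p = 2.31e-63, k = 60
#>   Q = 76.02 (df 59, p 0.0671), I2 = 22.4%
mrReport(list("AAomax|aneurysm" = an))[, c("method","or","orLower","orUpper","p","tier")]
#>            method   or orLower orUpper        p        tier
#> 1          IVW-RE 1.47    1.41    1.54 2.31e-63
#> 2        MR-Egger 1.26    1.08    1.48 4.28e-03 significant
#> 3 Weighted median 1.44    1.36    1.54 1.91e-31
#> 4   Weighted mode 1.42    1.27    1.59 2.05e-09
```

The IVW estimate recovers OR ≈ 1.5; all estimators agree in direction. At
this seed the Rücker decision switched the main model to MR-Egger (both the
heterogeneity drop and the intercept test crossed 0.05 by chance), so the
tier is reported on that row — the methods vignette discusses why Egger's
intercept test can fire under exposure measurement error and how I²GX
qualifies it.

See `vignettes/aaotraits-methods.Rmd` for the models, QC cascade,
generator design and numerical choices, and `runPipeline()` /
`pipelineConfig()` to run all stages (simulate → segment → extract → QC →
phenotype → associate → clump → MR) with a flow report.

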