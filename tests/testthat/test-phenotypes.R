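test_that("BSA formulas evaluate correctly and signal missing inputs", {
  expect_equal(computeBSA(170, 70), 0.007184 * 70^0.425 * 170^0.725)
  expect_equal(computeBSA(170, 70), 1.810, tolerance = 1e-3)
  expect_equal(computeBSA(170, 70, method = "mosteller"),
               sqrt(170 * 70 / 3600))
  expect_true(is.na(computeBSA(170, 0)))
  expect_true(is.na(computeBSA(NA, 70)))
  expect_equal(computeBSA(c(170, 160), c(70, NA)),
               c(computeBSA(170, 70), NA))
})

test_that("distensibility from the reference cohort means reads 2.3", {
  fr <- data.frame(areaCm2 = c(8.1, 7.2), diameterMm = c(32, 30))
  ph <- deriveAAoPhenotypes(fr, sbp = 133.5, dbp = 133.5 - 54.6, bsa = 1.9)
  expect_equal(ph$aaoMaxCm2, 8.1)
  expect_equal(ph$aaoMinCm2, 7.2)
  expect_equal(ph$distensibility, 1000 * 0.9 / (7.2 * 54.6))
  expect_equal(round(ph$distensibility, 1), 2.3)
})

test_that("degenerate phenotype inputs are handled", {
  fr <- data.frame(areaCm2 = c(8, 8), diameterMm = c(30, 30))
  expect_equal(deriveAAoPhenotypes(fr, 130, 80, 1.9)$distensibility, 0)
  ph <- deriveAAoPhenotypes(fr, 80, 130, 1.9)  # negative pulse pressure
  expect_true(is.na(ph$distensibility))
  expect_equal(ph$missingReason, "non_positive_pulse_pressure")
  ph <- deriveAAoPhenotypes(fr, NA, 80, 1.9)
  expect_equal(ph$missingReason, "missing_blood_pressure")
  ph <- deriveAAoPhenotypes(fr[1, ], 130, 80, 1.9)
  expect_equal(ph$missingReason, "single_retained_frame")
  ph <- deriveAAoPhenotypes(fr[0, ], 130, 80, 1.9)
  expect_equal(ph$missingReason, "no_retained_frames")
  # indexing identity is exact
  ph <- deriveAAoPhenotypes(data.frame(areaCm2 = c(7, 8)), 130, 80, 1.83)
  expect_equal(ph$aaoMaxIdx * ph$bsa, ph$aaoMaxCm2)
})

test_that("distensibility is invariant to area units", {
  frCm <- data.frame(areaCm2 = c(7.2, 8.1))
  frMm <- data.frame(areaCm2 = c(720, 810))  # same shape, mm^2 scale
  expect_equal(deriveAAoPhenotypes(frCm, 130, 80, 1.9)$distensibility,
               deriveAAoPhenotypes(frMm, 130, 80, 1.9)$distensibility)
})

test_that("inverse normal transform matches the quantile oracle", {
  expect_equal(inverseNormalTransform(c(3, 1, 2)),
               qnorm((c(3, 1, 2) - 0.5) / 3))
  expect_equal(inverseNormalTransform(c(3, 1, 2)),
               c(0.9674, -0.9674, 0), tolerance = 1e-4)
  # median of odd-length distinct input maps to 0
  expect_equal(inverseNormalTransform(c(10, 40, 20, 50, 30))[5], 0)
  # ties share the average-rank value
  out <- inverseNormalTransform(c(5, 5, 1))
  expect_equal(out[1], out[2])
  # NAs pass through without consuming ranks
  out <- inverseNormalTransform(c(3, NA, 1, 2))
  expect_true(is.na(out[2]))
  expect_equal(out[-2], qnorm((c(3, 1, 2) - 0.5) / 3))
  expect_error(inverseNormalTransform(rep(2, 5)), "all values equal")
  # large-sample moments approach N(0, 1)
  set.seed(71)
  z <- inverseNormalTransform(rnorm(10000))
  expect_lt(abs(mean(z)), 1e-8)
  expect_equal(sd(z), 1, tolerance = 0.01)
  # Blom offset variant
  expect_equal(inverseNormalTransform(c(3, 1, 2), offset = "blom"),
               qnorm((c(3, 1, 2) - 3 / 8) / 3.25))
})

test_that("reference table stratifies, balances and tracks trends", {
  ph <- data.frame(aaoMaxCm2 = rep(8, 10))
  tab <- referenceTable(ph, age = rep(60, 10), sex = rep("F", 10))
  filled <- tab[tab$n > 0, ]
  expect_true(all(filled$ageBin == "55-65"))
  expect_true(all(tab$n[tab$ageBin != "55-65"] == 0))
  # cell counts partition the cohort for each phenotype
  set.seed(82)
  n <- 200
  age <- runif(n, 40, 85)
  sexv <- sample(c("M", "F"), n, replace = TRUE)
  area <- 6 + 0.03 * age + rnorm(n, 0, 0.1)   # known age trend
  tab <- referenceTable(data.frame(aaoMaxCm2 = area), age, sexv)
  allRows <- tab[tab$sex == "All", ]
  expect_equal(sum(allRows$n), n)
  expect_equal(sum(tab$n[tab$sex == "Men"]) + sum(tab$n[tab$sex == "Women"]),
               n)
  expect_true(all(diff(allRows$mean[order(match(allRows$ageBin,
               c("<55", "55-65", "65-75", ">75")))]) > 0))
})

test_that("trait correlations report r with Fisher-z intervals", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  tc <- traitCorrelations(data.frame(a = x, b = x, c = -x))
  expect_equal(tc$r[tc$trait1 == "a" & tc$trait2 == "b"], 1)
  expect_equal(tc$r[tc$trait1 == "a" & tc$trait2 == "c"], -1)
  # zero variance flagged as NA
  tc <- traitCorrelations(data.frame(a = x, b = rep(2, 7)))
  expect_true(is.na(tc$r[1]))
  # interval for independent traits covers zero at ~95%
  set.seed(83)
  cover <- vapply(1:100, function(i) {
    d <- data.frame(a = rnorm(50), b = rnorm(50))
    tc <- traitCorrelations(d)
    tc$lower[1] <= 0 && 0 <= tc$upper[1]
  }, logical(1))
  expect_gte(sum(cover), 93)
})

test_that("end-to-end distensibility recovery tracks generative truth", {
  # canonical participant (cohort-mean areas) on a fine-resolution grid,
  # where the border-polygon half-pixel bias is small
  cfg <- cohortConfig(1, nFrames = 10, imageSize = c(448L, 448L),
                      pixelSpacing = c(0.25, 0.25),
                      areaDiastoleRange = c(7.2, 7.2),
                      areaSystoleRange = c(8.1, 8.1),
                      artefactProbability = 0, seed = 2)
  st <- generateCineStudy(cfg, "P001")
  gt <- groundTruth(st)
  fe <- extractStudyFeatures(st, masks = gt$masks, ellipse = FALSE)
  cv <- covariates(st)
  ph <- deriveAAoPhenotypes(fe, cv$sbp, cv$dbp,
                            computeBSA(cv$height, cv$weight))
  expect_lt(abs(ph$distensibility / gt$distensibility - 1), 0.02)
})

test_that("estimated distensibility regresses on truth with slope near 1", {
  cfg <- cohortConfig(300, nFrames = 5, imageSize = c(384L, 384L),
                      pixelSpacing = c(0.3, 0.3), artefactProbability = 0,
                      seed = 97)
  est <- truth <- numeric(300)
  for (i in 1:300) {
    st <- generateCineStudy(cfg, sprintf("P%03d", i))
    gt <- groundTruth(st)
    fe <- extractStudyFeatures(st, masks = gt$masks, ellipse = FALSE)
    cv <- covariates(st)
    est[i] <- deriveAAoPhenotypes(fe, cv$sbp, cv$dbp, 1.9)$distensibility
    truth[i] <- gt$distensibility
  }
  slope <- coef(lm(est ~ truth))[2]
  expect_gte(slope, 0.95)
  expect_lte(slope, 1.05)
})
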