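test_that("harmonization aligns, flips and removes correctly", {
  expo <- ssRow(ea = "A", oa = "G", eaf = 0.3, beta = 0.1)
  # same alleles: retained as-is
  h <- harmonizeInstruments(expo, ssRow(ea = "A", oa = "G", eaf = 0.3,
                                        beta = 0.05))
  expect_equal(instruments(h)$betaOutcome, 0.05)
  expect_false(instruments(h)$flipped)
  # swapped alleles: outcome beta sign flips
  h <- harmonizeInstruments(expo, ssRow(ea = "G", oa = "A", eaf = 0.7,
                                        beta = 0.05))
  expect_equal(instruments(h)$betaOutcome, -0.05)
  expect_true(instruments(h)$flipped)
  # strand-complement alleles: retained without flip
  h <- harmonizeInstruments(expo, ssRow(ea = "T", oa = "C", eaf = 0.3,
                                        beta = 0.05))
  expect_equal(instruments(h)$betaOutcome, 0.05)
  # incompatible alleles: removed
  h <- harmonizeInstruments(expo, ssRow(ea = "A", oa = "C", eaf = 0.3))
  expect_equal(removedVariants(h)$reason, "allele_mismatch")
})

test_that("palindromic variants follow the MAF 0.42 rule", {
  # ambiguous palindrome (MAF 0.45) removed
  h <- harmonizeInstruments(ssRow(ea = "A", oa = "T", eaf = 0.45),
                            ssRow(ea = "A", oa = "T", eaf = 0.45))
  expect_equal(nInstruments(h), 0L)
  expect_equal(removedVariants(h)$reason, "palindromic_ambiguous")
  # MAF 0.10 with concordant frequencies retained unflipped
  h <- harmonizeInstruments(ssRow(ea = "A", oa = "T", eaf = 0.10, beta = 0.1),
                            ssRow(ea = "A", oa = "T", eaf = 0.12, beta = 0.04))
  expect_equal(nInstruments(h), 1L)
  expect_equal(instruments(h)$betaOutcome, 0.04)
  expect_false(instruments(h)$flipped)
  # discordant frequencies imply a strand flip: sign inverted
  h <- harmonizeInstruments(ssRow(ea = "A", oa = "T", eaf = 0.10, beta = 0.1),
                            ssRow(ea = "A", oa = "T", eaf = 0.88, beta = 0.04))
  expect_equal(instruments(h)$betaOutcome, -0.04)
  # missing frequency on a palindrome removes it with reason
  h <- harmonizeInstruments(ssRow(ea = "G", oa = "C", eaf = 0.2),
                            ssRow(ea = "G", oa = "C", eaf = NA))
  expect_equal(removedVariants(h)$reason, "palindromic_missing_frequency")
})

test_that("F statistic follows the printed formula", {
  expect_equal(fStatistic(0.5, 4), 2)
  expect_equal(fStatistic(0, 100), 0)
  expect_equal(fStatistic(0.001, 31908), 0.001 * 31906 / 0.999,
               tolerance = 1e-12)
  expect_equal(fStatistic(0.001, 31908), 31.94, tolerance = 1e-3)
  expect_error(fStatistic(0.1, 2), "exceed 2")
})

test_that("instrument strength fills R2, F and the weak flag", {
  h <- makeHSet(bx = c(0.05, 0.002), sx = c(0.01, 0.01),
                by = c(0.02, 0.001), sy = c(0.012, 0.012), eaf = c(0.3, 0.3))
  h <- instrumentStrength(h)
  ins <- instruments(h)
  expect_equal(ins$r2Exposure, 2 * 0.3 * 0.7 * c(0.05, 0.002)^2)
  v <- 2 * 0.3 * 0.7
  expect_equal(ins$r2Outcome,
               c(0.02, 0.001)^2 * v / (c(0.02, 0.001)^2 * v + pi^2 / 3))
  expect_equal(ins$fStat, fStatistic(ins$r2Exposure, 30000))
  expect_identical(ins$weakInstrument, c(FALSE, TRUE))
})

test_that("Steiger filtering removes reverse-causal variants only", {
  # outcome explains nothing: nothing removed
  h <- makeHSet(bx = rep(0.05, 4), sx = 0.01, by = rep(0, 4), sy = 0.01)
  h <- steigerFilter(instrumentStrength(h, outcomeType = "continuous"))
  expect_equal(nInstruments(h), 4L)
  # much larger outcome R2 at large n: removed
  h <- makeHSet(bx = 0.03, sx = 0.01, by = 0.12, sy = 0.01)
  h <- steigerFilter(instrumentStrength(h, outcomeType = "continuous"))
  expect_equal(nInstruments(h), 0L)
  expect_equal(removedVariants(h)$reason, "steiger")
  # slightly larger outcome R2 at tiny n: test non-significant, retained
  h <- makeHSet(bx = 0.03, sx = 0.01, by = 0.032, sy = 0.01,
                nExp = 50, nOut = 50)
  h <- steigerFilter(instrumentStrength(h, outcomeType = "continuous"))
  expect_equal(nInstruments(h), 1L)
  expect_error(steigerFilter(makeHSet(0.1, 0.01, 0.1, 0.01)),
               "instrumentStrength")
})

test_that("Wald ratio arithmetic", {
  r <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(mrEstimate(r), 0.5)
  expect_equal(r@se, 0.1)
  expect_equal(mrEstimate(waldRatio(0.1, 0.01, 0, 0.01)), 0)
  expect_error(waldRatio(0, 0.01, 0.05, 0.01), "zero exposure")
})

test_that("IVW matches the weighted least-squares oracle and the Wald ratio", {
  h1 <- makeHSet(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.02)
  ivw1 <- mrIVW(h1)
  w1 <- waldRatio(0.1, 0.01, 0.05, 0.02)
  expect_equal(mrEstimate(ivw1), mrEstimate(w1))
  expect_equal(ivw1@se, w1@se)

  bx <- c(0.1, 0.2, 0.3); by <- 0.5 * bx
  h <- makeHSet(bx, sx = 0.001, by = by, sy = 0.01)
  ivw <- mrIVW(h)
  expect_equal(mrEstimate(ivw), 0.5, tolerance = 1e-12)
  expect_equal(ivw@Q, 0, tolerance = 1e-20)
  # oracle: weighted zero-intercept regression via lm
  set.seed(3)
  by2 <- 0.5 * bx + rnorm(3, 0, 0.01)
  h2 <- makeHSet(bx, 0.001, by2, 0.01)
  fit <- lm(by2 ~ bx - 1, weights = rep(1 / 0.01^2, 3))
  expect_equal(mrEstimate(mrIVW(h2)), unname(coef(fit)), tolerance = 1e-10)
})

test_that("estimates are invariant to instrument order", {
  set.seed(4)
  bx <- runif(8, 0.02, 0.1); by <- 0.4 * bx + rnorm(8, 0, 0.01)
  sy <- runif(8, 0.005, 0.02)
  h <- makeHSet(bx, 0.01, by, sy)
  perm <- sample(8)
  hp <- makeHSet(bx[perm], 0.01, by[perm], sy[perm])
  expect_equal(mrEstimate(mrIVW(h)), mrEstimate(mrIVW(hp)))
  expect_equal(mrIVW(h)@Q, mrIVW(hp)@Q)
  expect_equal(mrEstimate(mrEgger(h)), mrEstimate(mrEgger(hp)))
})

test_that("Egger recovers an exact affine relation", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  by <- 0.02 + 0.5 * bx
  e <- mrEgger(makeHSet(bx, 0.01, by, 0.01))
  expect_equal(mrEstimate(e), 0.5, tolerance = 1e-10)
  expect_equal(e@intercept, 0.02, tolerance = 1e-10)
  expect_equal(e@QPrime, 0, tolerance = 1e-16)
  # proportional effects give a zero intercept
  e0 <- mrEgger(makeHSet(bx, 0.01, 0.5 * bx, 0.01))
  expect_equal(e0@intercept, 0, tolerance = 1e-12)
  expect_error(mrEgger(makeHSet(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               "at least 3")
})

test_that("Q dominates Q-prime and I2 stays in range", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(4:20, 1)
    bx <- abs(rnorm(k, 0.08, 0.03)) + 0.01
    by <- 0.4 * bx + rnorm(k, 0.01, 0.02)
    sy <- runif(k, 0.005, 0.02)
    h <- makeHSet(bx, 0.01, by, sy)
    ivw <- mrIVW(h); egger <- mrEgger(h)
    expect_gte(ivw@Q + 1e-9, egger@QPrime)
    expect_gte(ivw@I2, 0); expect_lt(ivw@I2, 1)
  }
})

test_that("Ruecker selection needs both heterogeneity drop and intercept", {
  mk <- function(Q, QP = NULL, k = 10)
    new("MRResult", method = "IVW-RE", estimate = 0.1, se = 0.05,
        ciLower = 0, ciUpper = 0.2, p = 0.05, k = as.integer(k),
        Q = Q, QDf = k - 1, QP = if (is.null(QP))
          pchisq(Q, k - 1, lower.tail = FALSE) else QP,
        I2 = max(0, (Q - (k - 1)) / Q))
  mkE <- function(QPrime, interceptP)
    new("MRResult", method = "MR-Egger", estimate = 0.2, se = 0.05,
        ciLower = 0.1, ciUpper = 0.3, p = 0.01, k = 10L,
        Q = QPrime, QDf = 8, QP = NA_real_, I2 = NA_real_,
        intercept = 0.03, interceptSE = 0.01, interceptP = interceptP,
        QPrime = QPrime, I2GX = 0.97)
  # neither criterion met -> IVW-RE
  expect_equal(ruckerSelect(mk(9), mkE(8.5, 0.8))$selected, "IVW-RE")
  # both met -> MR-Egger (Q - Q' = 12 >> chi2_1 critical, intercept p 0.01)
  expect_equal(ruckerSelect(mk(20), mkE(8, 0.01))$selected, "MR-Egger")
  # heterogeneity drop alone is not enough
  expect_equal(ruckerSelect(mk(20), mkE(8, 0.5))$selected, "IVW-RE")
  # significant intercept alone is not enough
  expect_equal(ruckerSelect(mk(9), mkE(8.8, 0.01))$selected, "IVW-RE")
})

test_that("weighted median interpolates and resists an outlier", {
  bx <- rep(0.1, 3); sy <- rep(0.01, 3)
  h <- makeHSet(bx, 0.01, c(0.04, 0.05, 0.06), sy)  # ratios 0.4 0.5 0.6
  expect_equal(mrEstimate(mrWeightedMedian(h, bootstrapReps = 50)), 0.5)
  # 9 consistent ratios at 0.5, one wild outlier
  bx <- rep(0.1, 10)
  by <- c(rep(0.05, 9), 0.5)
  h <- makeHSet(bx, 0.005, by, rep(0.01, 10))
  est <- mrEstimate(mrWeightedMedian(h, bootstrapReps = 50))
  expect_lt(abs(est - 0.5), 0.02)
  # weight concentration pulls the estimate to the dominant variant
  h <- makeHSet(c(0.5, 0.05, 0.05), 0.001, c(0.35, 0.01, 0.01),
                c(0.001, 0.5, 0.5))
  expect_equal(mrEstimate(mrWeightedMedian(h, bootstrapReps = 50)), 0.7,
               tolerance = 1e-6)
  expect_error(mrWeightedMedian(makeHSet(0.1, 0.01, 0.1, 0.01)), "at least 3")
})

test_that("weighted mode finds the plurality effect", {
  h <- makeHSet(rep(0.1, 4), 0.01, rep(0.06, 4), 0.01)
  expect_equal(mrEstimate(mrWeightedMode(h, bootstrapReps = 50)), 0.6,
               tolerance = 1e-9)
  # 7 ratios at 0.5, 3 at 1.5 -> mode near 0.5
  bx <- rep(0.1, 10)
  by <- c(rep(0.05, 7), rep(0.15, 3)) + seq(-0.0015, 0.0015, length.out = 10)
  h <- makeHSet(bx, 0.005, by, rep(0.01, 10))
  expect_lt(abs(mrEstimate(mrWeightedMode(h, bootstrapReps = 50)) - 0.5),
            0.1)
  # infinite bandwidth flattens the kernel toward the weighted mean
  wide <- mrEstimate(mrWeightedMode(h, bandwidthFactor = 500,
                                    bootstrapReps = 50))
  wmean <- sum((by / bx) * (bx^2 / 0.01^2)) / sum(bx^2 / 0.01^2)
  expect_lt(abs(wide - wmean), 0.05)
})

test_that("bootstrap SEs are reproducible for a fixed seed", {
  set.seed(6)
  bx <- runif(6, 0.05, 0.15)
  h <- makeHSet(bx, 0.01, 0.3 * bx + rnorm(6, 0, 0.01), 0.01)
  a <- mrWeightedMedian(h, bootstrapReps = 200, seed = 9)
  b <- mrWeightedMedian(h, bootstrapReps = 200, seed = 9)
  expect_identical(a@se, b@se)
})

test_that("the full analysis battery and report tier correctly", {
  ss <- generateMRSummaryStats(mrSimConfig(20, theta = log(1.5), seed = 77))
  h <- harmonizeInstruments(ss$exposure, ss$outcome,
                            exposureName = "AAomax", outcomeName = "aneurysm")
  an <- mrAnalyze(h, bootstrapReps = 100, seed = 1)
  expect_s4_class(an$ivw, "MRResult")
  expect_s4_class(an$egger, "MRResult")
  expect_true(an$selectedModel %in% c("IVW-RE", "MR-Egger"))
  rep <- mrReport(list("AAomax|aneurysm" = an))
  expect_setequal(rep$method, c("IVW-RE", "MR-Egger", "Weighted median",
                                "Weighted mode"))
  mainRow <- rep[rep$method == an$selectedModel, ]
  expect_true(mainRow$tier %in% c("significant", "suggestive", "null"))
  expect_equal(rep$or, exp(rep$estimate))

  expect_equal(significanceTier(0.003), "significant")
  expect_equal(significanceTier(0.03), "suggestive")
  expect_equal(significanceTier(0.2), "null")
  expect_equal(significanceTier(0.004999), "significant")
})

test_that("Steiger leaves null-outcome instruments untouched end to end", {
  ss <- generateMRSummaryStats(mrSimConfig(15, theta = 0, seed = 88))
  h <- harmonizeInstruments(ss$exposure, ss$outcome)
  an <- mrAnalyze(h, steiger = TRUE, bootstrapReps = 50)
  expect_equal(sum(removedVariants(an$set)$reason == "steiger"), 0L)
})
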