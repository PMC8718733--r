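test_that("variant filters apply MAF and INFO thresholds symmetrically", {
  rec <- data.frame(SNP = paste0("v", 1:5),
                    EAF = c(0.004, 0.996, 0.3, 0.2, 0.5),
                    INFO = c(NA, NA, 0.29, NA, 0.9))
  kept <- filterVariants(rec)
  expect_identical(kept$SNP, c("v4", "v5"))
  expect_error(filterVariants(data.frame(SNP = "x")), "EAF")
})

test_that("association recovers a noiseless effect exactly", {
  set.seed(31)
  d <- sample(0:2, 80, replace = TRUE)
  a <- associateVariant(d, 0.5 * d)
  expect_equal(a$beta, 0.5, tolerance = 1e-12)
  expect_lt(a$se, 1e-12)
})

test_that("degenerate designs are flagged, not fitted", {
  y <- rnorm(30)
  a <- associateVariant(rep(1, 30), y)
  expect_equal(a$flag, "constant_dosage")
  expect_true(is.na(a$beta))
  d <- sample(0:2, 30, replace = TRUE)
  a <- associateVariant(d, y, covariates = cbind(conf = 2 * d))
  expect_equal(a$flag, "collinear")
})

test_that("null association scan holds its type-I error rate", {
  g <- generateGenotypes(300, 2000, seed = 17)
  set.seed(18)
  y <- rnorm(300)
  covM <- cbind(age = rnorm(300), sex = rbinom(300, 1, 0.5))
  res <- associateAll(g$dosages, y, covM)
  expect_gte(mean(res$p < 0.05), 0.03)
  expect_lte(mean(res$p < 0.05), 0.07)
})

test_that("covariate adjustment matches lm()", {
  set.seed(33)
  d <- sample(0:2, 60, replace = TRUE)
  age <- rnorm(60)
  y <- 0.3 * d + 0.5 * age + rnorm(60)
  a <- associateVariant(d, y, cbind(age = age))
  fit <- summary(lm(y ~ d + age))$coefficients
  expect_equal(a$beta, fit["d", 1], tolerance = 1e-10)
  expect_equal(a$se, fit["d", 2], tolerance = 1e-10)
  expect_equal(a$p, fit["d", 4], tolerance = 1e-10)
})

test_that("greedy clumping resolves the three-variant example", {
  assoc <- data.frame(snp = c("v1", "v2", "v3"),
                      p = c(1e-10, 1e-9, 1e-6),
                      pos = c(1e6, 2e6, 3e6))
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.5
  rownames(r2) <- colnames(r2) <- assoc$snp
  leads <- greedyClump(assoc, r2)
  expect_identical(leads$snp, c("v1", "v3"))
  expect_identical(leads$genomewideSignificant, c(TRUE, FALSE))
  # a single significant variant clumps to itself
  one <- greedyClump(assoc[1, ], matrix(1, 1, 1, dimnames = list("v1", "v1")))
  expect_identical(one$snp, "v1")
  # nothing passing the threshold gives an empty lead set
  weak <- assoc; weak$p <- c(0.1, 0.2, 0.3)
  expect_equal(nrow(greedyClump(weak, r2)), 0L)
})

test_that("clumping agrees with a step-by-step enumeration oracle", {
  # oracle: literal restatement of the procedure, no vectorized shortcuts
  clumpOracle <- function(assoc, r2, pThr = 1e-5, r2Thr = 0.005, win = 5e6) {
    cand <- assoc[assoc$p < pThr, , drop = FALSE]
    cand <- cand[order(cand$p, cand$pos), , drop = FALSE]
    leads <- character(0)
    while (nrow(cand) > 0) {
      lead <- cand[1, ]
      leads <- c(leads, lead$snp)
      keep <- logical(nrow(cand))
      for (j in seq_len(nrow(cand))) {
        linked <- r2[lead$snp, cand$snp[j]] >= r2Thr &&
          abs(cand$pos[j] - lead$pos) <= win
        keep[j] <- !linked
      }
      cand <- cand[keep, , drop = FALSE]
    }
    leads
  }
  set.seed(49)
  for (i in 1:40) {
    m <- sample(2:12, 1)
    assoc <- data.frame(snp = sprintf("s%02d", 1:m),
                        p = 10^runif(m, -12, -2),
                        pos = sort(sample(1:20, m)) * 1e6)
    L <- matrix(runif(m * m), m)
    r2 <- (L + t(L)) / 2; diag(r2) <- 1
    r2 <- ifelse(r2 > 0.6, r2, 0)     # sparse LD
    rownames(r2) <- colnames(r2) <- assoc$snp
    leads <- greedyClump(assoc, r2)
    expect_identical(leads$snp, clumpOracle(assoc, r2))
    # leads are mutually unlinked within the window
    if (nrow(leads) > 1) {
      for (a in seq_len(nrow(leads) - 1)) for (b in (a + 1):nrow(leads)) {
        linked <- r2[leads$snp[a], leads$snp[b]] >= 0.005 &&
          abs(leads$pos[a] - leads$pos[b]) <= 5e6
        expect_false(linked)
      }
    }
  }
})

test_that("a strong causal variant is almost always the clump lead", {
  hits <- vapply(1:20, function(r) {
    g <- generateGenotypes(400, 20, ldBlockSize = 5, withinBlockR = 0.6,
                           seed = 100 + r)
    set.seed(200 + r)
    causal <- 8L
    y <- 0.8 * g$dosages[, causal] + rnorm(400)
    assoc <- associateAll(g$dosages, y, variants = g$variants)
    assoc$pos <- assoc$pos
    leads <- greedyClump(assoc, ldMatrix(g$dosages), pThreshold = 1e-5)
    length(leads$snp) > 0 && leads$snp[1] == g$variants$snp[causal]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("loci span +/- 1 Mb and merge across traits keeping the best lead", {
  leadA <- data.frame(snp = "a1", chr = 1L, pos = 3e6, p = 1e-9)
  loci <- defineLoci(list(AAomax = leadA))
  expect_equal(loci$start, 2e6)
  expect_equal(loci$end, 4e6)
  leadB <- data.frame(snp = "b1", chr = 1L, pos = 4.5e6, p = 1e-12)
  merged <- defineLoci(list(AAomax = leadA, AAomin = leadB))
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$leadSnp, "b1")
  expect_identical(merged$traits, "AAomax,AAomin")
  # non-overlapping leads stay separate loci
  leadC <- data.frame(snp = c("c1", "c2"), chr = 1L, pos = c(3e6, 9e6),
                      p = c(1e-9, 1e-10))
  expect_equal(nrow(defineLoci(list(AAomax = leadC))), 2L)
  # different chromosomes never merge
  leadD <- data.frame(snp = c("d1", "d2"), chr = c(1L, 2L), pos = c(3e6, 3e6),
                      p = c(1e-9, 1e-10))
  expect_equal(nrow(defineLoci(list(AAomax = leadD))), 2L)
})

test_that("genomic lambda behaves as a calibrated inflation measure", {
  expect_equal(genomicLambda(rep(0.5, 200)), 1)
  set.seed(35)
  p <- runif(10000)
  expect_lt(abs(genomicLambda(p) - 1), 0.05)
  expect_gt(genomicLambda(p / 2), 1)
})
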