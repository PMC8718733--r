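# shared fixture builders (everything is generated in code)

# filled disk mask of radius r centred in a (2r+margin) square grid
diskMask <- function(r, margin = 20L) {
  n <- 2L * r + margin
  c0 <- (n + 1) / 2
  d2 <- (row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2
  (d2 <= r^2) * 1L
}

# axis-aligned filled block mask
blockMask <- function(n = 20L, rows = 6:15, cols = 6:15) {
  m <- matrix(0L, n, n)
  m[rows, cols] <- 1L
  m
}

# numeric perimeter of an ellipse with semi-axes a, b (arc-length integral)
ellipsePerimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

# frame-features table built directly (bypasses imaging) for QC-rule tests
featureRows <- function(areas, roundness = 0.95, sigma = 2, empty = FALSE) {
  n <- length(areas)
  data.frame(frame = seq_len(n), areaCm2 = areas,
             pixelCountAreaCm2 = areas, perimeterMm = 30,
             diameterMm = 30, axisMajorMm = 31, axisMinorMm = 29,
             roundness = rep_len(roundness, n),
             noiseSigma = rep_len(sigma, n),
             emptyMask = rep_len(empty, n),
             borderTouching = FALSE)
}

cleanCovariates <- function() {
  list(sbp = 133, dbp = 79, height = 170, weight = 75, age = 60, sex = "F")
}

# harmonized instrument set built directly from effect vectors
makeHSet <- function(bx, sx, by, sy, eaf = NULL, nExp = 30000, nOut = 20000) {
  k <- length(bx)
  if (is.null(eaf)) eaf <- rep(0.3, k)
  ins <- data.frame(snp = sprintf("v%03d", seq_len(k)),
                    betaExposure = bx, seExposure = sx,
                    betaOutcome = by, seOutcome = sy,
                    eaf = eaf, eafOutcome = eaf,
                    nExposure = nExp, nOutcome = nOut,
                    flipped = FALSE, stringsAsFactors = FALSE)
  new("HarmonizedInstrumentSet", instruments = ins,
      removed = data.frame(snp = character(), reason = character(),
                           stringsAsFactors = FALSE),
      exposure = "x", outcome = "y")
}

# one-row summary-stat table builder for harmonization tests
ssRow <- function(snp = "rs1", ea, oa, eaf, beta = 0.1, se = 0.01,
                  n = 30000) {
  data.frame(SNP = snp, CHR = 1L, BP = 1e6, EA = ea, OA = oa, EAF = eaf,
             BETA = beta, SE = se, P = 1e-9, N = n, stringsAsFactors = FALSE)
}
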