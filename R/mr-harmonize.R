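complementAlleles <- function(a) chartr("ACGT", "TGCA", a)

isPalindromic <- function(ea, oa) ea == complementAlleles(oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table to the exposure's effect-allele orientation:
#' swapped alleles flip the outcome beta; strand flips are resolved by
#' complementing. Palindromic variants (A/T or G/C), whose strand cannot be
#' read from the alleles, are resolved with allele-frequency information --
#' removed when the minor allele frequency exceeds
#' \code{palindromicMafThreshold} (default 0.42, where frequency becomes
#' uninformative) or when frequency is missing, and otherwise aligned so the
#' exposure and outcome frequencies fall on the same side of 0.5.
#'
#' @param exposure,outcome data.frames in the summary-statistic schema
#'   (SNP, EA, OA, EAF, BETA, SE, N, ...).
#' @param palindromicMafThreshold MAF above which palindromic variants are
#'   dropped (default 0.42).
#' @param exposureName,outcomeName labels for reporting.
#' @return a \linkS4class{HarmonizedInstrumentSet}.
#' @export
harmonizeInstruments <- function(exposure, outcome,
                                 palindromicMafThreshold = 0.42,
                                 exposureName = "exposure",
                                 outcomeName = "outcome") {
  shared <- intersect(exposure$SNP, outcome$SNP)
  ex <- exposure[match(shared, exposure$SNP), ]
  ou <- outcome[match(shared, outcome$SNP), ]
  keep <- list(); removed <- list()
  for (i in seq_along(shared)) {
    eEA <- ex$EA[i]; eOA <- ex$OA[i]
    oEA <- ou$EA[i]; oOA <- ou$OA[i]
    by <- ou$BETA[i]; eafO <- ou$EAF[i]
    flipped <- FALSE
    drop <- function(reason)
      data.frame(snp = shared[i], reason = reason, stringsAsFactors = FALSE)
    if (isPalindromic(eEA, eOA)) {
      if (is.na(ex$EAF[i]) || is.na(eafO)) {
        removed[[length(removed) + 1L]] <- drop("palindromic_missing_frequency")
        next
      }
      maf <- min(ex$EAF[i], 1 - ex$EAF[i])
      if (maf > palindromicMafThreshold) {
        removed[[length(removed) + 1L]] <- drop("palindromic_ambiguous")
        next
      }
      # letter-align first (A/T vs T/A), then frequency decides the strand
      if (oEA == eOA && oOA == eEA) { by <- -by; eafO <- 1 - eafO }
      else if (!(oEA == eEA && oOA == eOA)) {
        removed[[length(removed) + 1L]] <- drop("allele_mismatch")
        next
      }
      if ((ex$EAF[i] < 0.5) != (eafO < 0.5)) {
        by <- -by; eafO <- 1 - eafO; flipped <- TRUE
      }
    } else {
      cEA <- complementAlleles(oEA); cOA <- complementAlleles(oOA)
      if (oEA == eEA && oOA == eOA) {
        # aligned as-is
      } else if (oEA == eOA && oOA == eEA) {
        by <- -by; eafO <- 1 - eafO; flipped <- TRUE
      } else if (cEA == eEA && cOA == eOA) {
        # strand flip only
      } else if (cEA == eOA && cOA == eEA) {
        by <- -by; eafO <- 1 - eafO; flipped <- TRUE
      } else {
        removed[[length(removed) + 1L]] <- drop("allele_mismatch")
        next
      }
    }
    keep[[length(keep) + 1L]] <- data.frame(
      snp = shared[i],
      betaExposure = ex$BETA[i], seExposure = ex$SE[i],
      betaOutcome = by, seOutcome = ou$SE[i],
      eaf = ex$EAF[i], eafOutcome = eafO,
      nExposure = ex$N[i], nOutcome = ou$N[i],
      flipped = flipped, stringsAsFactors = FALSE)
  }
  emptyIns <- data.frame(snp = character(), betaExposure = numeric(),
                         seExposure = numeric(), betaOutcome = numeric(),
                         seOutcome = numeric(), eaf = numeric(),
                         eafOutcome = numeric(), nExposure = numeric(),
                         nOutcome = numeric(), flipped = logical(),
                         stringsAsFactors = FALSE)
  new("HarmonizedInstrumentSet",
      instruments = if (length(keep)) do.call(rbind, keep) else emptyIns,
      removed = if (length(removed)) do.call(rbind, removed) else
        data.frame(snp = character(), reason = character(),
                   stringsAsFactors = FALSE),
      exposure = exposureName, outcome = outcomeName)
}

#' Per-variant explained variance and F statistic
#'
#' For a unit-variance (inverse-normal transformed) exposure the variance a
#' variant explains is \eqn{R^2 = 2\,maf(1-maf)\,\beta_X^2}. For a binary
#' outcome the explained variance is put on the latent liability scale with
#' the logistic approximation
#' \eqn{R^2 = \beta_Y^2 v / (\beta_Y^2 v + \pi^2/3)}, \eqn{v = 2\,maf(1-maf)}.
#' Instrument strength is \eqn{F = R^2 (n - 2) / (1 - R^2)}; variants with
#' \eqn{F \le 10} are flagged as weak (not removed).
#'
#' @param hset a \linkS4class{HarmonizedInstrumentSet}.
#' @param outcomeType \code{"binary"} (default) or \code{"continuous"}.
#' @return the set with \code{r2Exposure}, \code{r2Outcome}, \code{fStat},
#'   \code{weakInstrument} filled.
#' @export
instrumentStrength <- function(hset, outcomeType = c("binary", "continuous")) {
  outcomeType <- match.arg(outcomeType)
  ins <- hset@instruments
  if (nrow(ins)) {
    if (any(ins$nExposure <= 2)) stop("exposure sample size must exceed 2")
    maf <- pmin(ins$eaf, 1 - ins$eaf)
    v <- 2 * maf * (1 - maf)
    ins$r2Exposure <- v * ins$betaExposure^2
    ins$r2Outcome <- if (outcomeType == "binary")
      ins$betaOutcome^2 * v / (ins$betaOutcome^2 * v + pi^2 / 3)
    else v * ins$betaOutcome^2
    ins$fStat <- fStatistic(ins$r2Exposure, ins$nExposure)
    ins$weakInstrument <- ins$fStat <= 10
  }
  initialize(hset, instruments = ins)
}

#' F statistic from explained variance
#'
#' \eqn{F = (R^2 (n - 2)) / (1 - R^2)}.
#'
#' @param r2 variance explained by the variant. @param n sample size (> 2).
#' @return F. Vectorized.
#' @examples
#' fStatistic(0.5, 4)  # 2
#' @export
fStatistic <- function(r2, n) {
  if (any(n <= 2)) stop("n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Steiger filtering against reverse causation
#'
#' Removes a variant when it explains more outcome than exposure variance
#' \emph{and} the difference is statistically significant: the two implied
#' correlations (sqrt of the R^2 values) are compared with a two-sided
#' Fisher-z test using the two samples' sizes.
#'
#' @param hset a \linkS4class{HarmonizedInstrumentSet} with R^2 columns
#'   filled (see \code{\link{instrumentStrength}}).
#' @param alpha test level (default 0.05).
#' @return the set with Steiger-removed variants moved to the removed table
#'   and a \code{steigerRemoved} flag on the instrument rows.
#' @export
steigerFilter <- function(hset, alpha = 0.05) {
  ins <- hset@instruments
  if (is.null(ins$r2Exposure))
    stop("run instrumentStrength() before steigerFilter()")
  if (!nrow(ins)) return(hset)
  rX <- sqrt(pmin(ins$r2Exposure, 1 - 1e-12))
  rY <- sqrt(pmin(ins$r2Outcome, 1 - 1e-12))
  z <- (atanh(rY) - atanh(rX)) /
    sqrt(1 / (ins$nOutcome - 3) + 1 / (ins$nExposure - 3))
  p <- 2 * pnorm(-abs(z))
  ins$steigerRemoved <- ins$r2Outcome > ins$r2Exposure & p < alpha
  rem <- hset@removed
  if (any(ins$steigerRemoved))
    rem <- rbind(rem, data.frame(snp = ins$snp[ins$steigerRemoved],
                                 reason = "steiger",
                                 stringsAsFactors = FALSE))
  initialize(hset, instruments = ins[!ins$steigerRemoved, , drop = FALSE],
             removed = rem)
}
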