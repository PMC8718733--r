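#' Body surface area
#'
#' Du Bois formula by default:
#' \eqn{0.007184 \, weight^{0.425} \, height^{0.725}} (weight kg, height cm);
#' Mosteller (\eqn{\sqrt{height \cdot weight / 3600}}) selectable. Missing or
#' non-positive inputs yield \code{NA}, which drives the QC exclusion for the
#' indexed traits.
#'
#' @param height cm (vectorized).
#' @param weight kg (vectorized).
#' @param method \code{"dubois"} (default) or \code{"mosteller"}.
#' @return BSA in m^2, \code{NA} where inputs are unusable.
#' @examples
#' computeBSA(170, 70)                        # ~1.810
#' computeBSA(170, 70, method = "mosteller")  # ~1.818
#' @export
computeBSA <- function(height, weight, method = c("dubois", "mosteller")) {
  method <- match.arg(method)
  bad <- is.na(height) | is.na(weight) | height <= 0 | weight <= 0
  out <- switch(method,
    dubois = 0.007184 * weight^0.425 * height^0.725,
    mosteller = sqrt(height * weight / 3600))
  out[bad] <- NA_real_
  out
}

#' Derive per-participant ascending aortic phenotypes
#'
#' AAomax and AAomin are the maximum and minimum of the per-frame lumen
#' areas over QC-retained frames (the systolic and diastolic extremes of the
#' cycle); distensibility is the relative systolic enlargement per unit
#' pulse pressure,
#' \deqn{AAo_{dist} = \frac{AAo_{max} - AAo_{min}}{AAo_{min} \cdot PP},}
#' reported in 10^-3 mmHg^-1. Areas and diameters are additionally indexed
#' to BSA.
#'
#' @param features data.frame of retained frames (needs \code{areaCm2},
#'   \code{diameterMm}).
#' @param sbp,dbp mmHg (NA allowed; distensibility then missing).
#' @param bsa m^2 (NA allowed; indexed values then missing).
#' @return one-row data.frame: \code{aaoMaxCm2}, \code{aaoMinCm2},
#'   \code{aaoMaxIdx}, \code{aaoMinIdx} (cm^2/m^2), \code{diameterMaxMm},
#'   \code{diameterMinMm}, \code{distensibility} (10^-3 mmHg^-1), \code{pp},
#'   \code{bsa}, \code{missingReason}.
#' @examples
#' fr <- data.frame(areaCm2 = c(7.2, 8.1), diameterMm = c(30, 32))
#' deriveAAoPhenotypes(fr, sbp = 133.5, dbp = 78.9, bsa = 1.9)
#' @export
deriveAAoPhenotypes <- function(features, sbp, dbp, bsa = NA_real_) {
  empty <- data.frame(aaoMaxCm2 = NA_real_, aaoMinCm2 = NA_real_,
                      aaoMaxIdx = NA_real_, aaoMinIdx = NA_real_,
                      diameterMaxMm = NA_real_, diameterMinMm = NA_real_,
                      distensibility = NA_real_, pp = NA_real_,
                      bsa = NA_real_, missingReason = NA_character_,
                      stringsAsFactors = FALSE)
  areas <- features$areaCm2[!is.na(features$areaCm2)]
  if (!length(areas)) {
    empty$missingReason <- "no_retained_frames"
    return(empty)
  }
  out <- empty
  out$aaoMaxCm2 <- max(areas)
  out$aaoMinCm2 <- min(areas)
  if (!is.null(features$diameterMm) && any(!is.na(features$diameterMm))) {
    out$diameterMaxMm <- max(features$diameterMm, na.rm = TRUE)
    out$diameterMinMm <- min(features$diameterMm, na.rm = TRUE)
  }
  out$bsa <- bsa
  if (!is.na(bsa) && bsa > 0) {
    out$aaoMaxIdx <- out$aaoMaxCm2 / bsa
    out$aaoMinIdx <- out$aaoMinCm2 / bsa
  }
  pp <- sbp - dbp
  if (is.na(pp) || length(areas) < 2L) {
    out$missingReason <- if (is.na(pp)) "missing_blood_pressure" else
      "single_retained_frame"
  } else if (pp <= 0) {
    out$missingReason <- "non_positive_pulse_pressure"
    out$pp <- pp
  } else {
    out$pp <- pp
    out$distensibility <-
      1000 * (out$aaoMaxCm2 - out$aaoMinCm2) / (out$aaoMinCm2 * pp)
  }
  out
}

#' Rank-based inverse normal transform
#'
#' \eqn{\Phi^{-1}((rank - c)/(n - 2c + 1))} with offset \eqn{c}: the default
#' half offset gives \eqn{\Phi^{-1}((rank - 0.5)/n)}; Blom's 3/8 offset is
#' selectable. Ties get average ranks; missing values stay missing and do
#' not consume ranks.
#'
#' @param values numeric vector (>= 2 non-missing, not all equal).
#' @param offset \code{"half"} (default) or \code{"blom"}.
#' @return transformed vector, same length and NA pattern.
#' @examples
#' inverseNormalTransform(c(3, 1, 2))
#' @export
inverseNormalTransform <- function(values, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 non-missing values")
  if (diff(range(values[ok])) == 0)
    stop("all values equal: ranks are undefined")
  c0 <- if (offset == "half") 0.5 else 3 / 8
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - c0) / (n - 2 * c0 + 1))
  out
}

#' Age- and sex-stratified reference table
#'
#' Mean (SD) and N per cell for each phenotype, stratified by sex
#' (All/Men/Women) and age bins <55, 55-65, 65-75, >75. Empty strata are
#' reported with N = 0 and missing mean/SD.
#'
#' @param phenotypes data.frame with one row per participant containing the
#'   phenotype columns to summarize.
#' @param age,sex vectors aligned with \code{phenotypes}; \code{sex} coded
#'   \code{"M"}/\code{"F"}.
#' @param columns phenotype columns to tabulate (default: areas, indexed
#'   areas, distensibility and diameters when present).
#' @return data.frame: phenotype, sex, ageBin, mean, sd, n.
#' @export
referenceTable <- function(phenotypes, age, sex,
                           columns = intersect(
                             c("aaoMinCm2", "aaoMinIdx", "aaoMaxCm2",
                               "aaoMaxIdx", "distensibility",
                               "diameterMinMm", "diameterMaxMm"),
                             names(phenotypes))) {
  stopifnot(length(age) == nrow(phenotypes), length(sex) == nrow(phenotypes))
  bins <- cut(age, c(-Inf, 55, 65, 75, Inf),
              labels = c("<55", "55-65", "65-75", ">75"), right = FALSE)
  sexGroups <- list(All = rep(TRUE, length(sex)), Men = sex == "M",
                    Women = sex == "F")
  grid <- expand.grid(phenotype = columns, sex = names(sexGroups),
                      ageBin = levels(bins), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- sexGroups[[grid$sex[i]]] & bins == grid$ageBin[i]
    v <- phenotypes[[grid$phenotype[i]]][sel]
    v <- v[!is.na(v)]
    data.frame(grid[i, ], mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise trait correlations with Fisher-z confidence intervals
#'
#' Pearson product-moment correlation for every pair of columns, with the
#' 95\% interval from the Fisher z transform on complete pairs.
#'
#' @param traits data.frame of numeric phenotype columns.
#' @return data.frame: trait1, trait2, r, lower, upper, p, n. Pairs with
#'   fewer than 3 complete observations or zero variance are flagged with
#'   \code{NA} estimates.
#' @export
traitCorrelations <- function(traits) {
  nms <- names(traits)
  pairs <- utils::combn(nms, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- traits[[pairs[1, i]]]; y <- traits[[pairs[2, i]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    base <- data.frame(trait1 = pairs[1, i], trait2 = pairs[2, i],
                       r = NA_real_, lower = NA_real_, upper = NA_real_,
                       p = NA_real_, n = n, stringsAsFactors = FALSE)
    if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(base)
    r <- cor(x[ok], y[ok])
    z <- atanh(r); sez <- 1 / sqrt(n - 3)
    base$r <- r
    base$lower <- tanh(z - qnorm(0.975) * sez)
    base$upper <- tanh(z + qnorm(0.975) * sez)
    base$p <- 2 * pnorm(-abs(z / sez))
    base
  })
  do.call(rbind, res)
}
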