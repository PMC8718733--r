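#' The 3x3 noise-estimation kernel
#'
#' Difference-of-Laplacians kernel used by the fast noise-variance estimator;
#' rows and columns sum to zero, so the estimate ignores constant offsets and
#' linear ramps.
#'
#' @return 3x3 integer matrix.
#' @export
noiseKernel <- function() {
  matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3, byrow = TRUE)
}

#' QC thresholds
#'
#' The frame- and participant-level exclusion thresholds: roundness below
#' 0.85, area below 3 or above 20 cm^2, more than 25\% of frames excluded,
#' mean consecutive-frame area difference above 0.3 cm^2, inter-pixel noise
#' sigma above 4.1 (on a 0--255-like brightness scale; configurable because
#' the calibration scale of acquisition data may differ), 80 px centred crop
#' for the noise estimate.
#'
#' @param roundnessMin,areaMinCm2,areaMaxCm2 frame-level rules.
#' @param maxExcludedFraction participant-level excluded-frame budget.
#' @param maxMeanFrameDiffCm2 participant-level mean |area(i+1) - area(i)|
#'   bound over consecutive retained frames.
#' @param sigmaMax flow-void artefact rule; excludes AAomax and AAodist
#'   (not AAomin).
#' @param cropSize centred crop for the noise estimate.
#' @return list of class \code{"qcThresholds"}.
#' @export
qcThresholds <- function(roundnessMin = 0.85, areaMinCm2 = 3,
                         areaMaxCm2 = 20, maxExcludedFraction = 0.25,
                         maxMeanFrameDiffCm2 = 0.3, sigmaMax = 4.1,
                         cropSize = 80L) {
  stopifnot(roundnessMin > 0, areaMinCm2 > 0, areaMaxCm2 > areaMinCm2,
            maxExcludedFraction > 0, maxMeanFrameDiffCm2 > 0, sigmaMax > 0,
            cropSize >= 3)
  structure(list(roundnessMin = roundnessMin, areaMinCm2 = areaMinCm2,
                 areaMaxCm2 = areaMaxCm2,
                 maxExcludedFraction = maxExcludedFraction,
                 maxMeanFrameDiffCm2 = maxMeanFrameDiffCm2,
                 sigmaMax = sigmaMax, cropSize = as.integer(cropSize)),
            class = "qcThresholds")
}

#' Relative roundness of a contour
#'
#' The isoperimetric ratio \eqn{R_r = 4 \pi \, area / perimeter^2}: 1 for a
#' perfect circle, approaching 0 for an almost flat ellipse.
#'
#' @param area enclosed area (squared length units).
#' @param perimeter contour length (same length units); must be positive.
#' @return dimensionless roundness. Vectorized.
#' @examples
#' relativeRoundness(pi * 4, 2 * pi * 2)  # circle -> 1
#' relativeRoundness(1, 4)                # unit square -> pi/4
#' @export
relativeRoundness <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Fast inter-pixel noise estimate (Immerkaer)
#'
#' Convolves the centred \code{crop} x \code{crop} region with the
#' \code{\link{noiseKernel}} wherever the 3x3 kernel fits and returns
#' \deqn{\sigma_n = \sqrt{\pi/2} \; \frac{1}{6 (W-2)(H-2)} \sum |I * N|,}
#' an estimate of the SD of i.i.d. Gaussian pixel noise that is blind to
#' smooth image structure. High values flag flow-void artefacts, which
#' manifest as high-frequency brightness fluctuation around the lumen.
#'
#' @param image numeric brightness matrix.
#' @param crop side of the centred square crop; cropping is skipped when the
#'   image is already no larger. The cropped region must be at least 3x3.
#' @return estimated noise SD (brightness units).
#' @examples
#' interpixelVariance(matrix(5, 50, 50))  # constant image -> 0
#' @export
interpixelVariance <- function(image, crop = 80L) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  ch <- min(H, crop); cw <- min(W, crop)
  if (ch < 3L || cw < 3L) stop("cropped image must be at least 3x3")
  r0 <- floor((H - ch) / 2); c0 <- floor((W - cw) / 2)
  I <- image[(r0 + 1):(r0 + ch), (c0 + 1):(c0 + cw), drop = FALSE]
  # 3x3 convolution by shifted sums over the valid interior
  s <- function(dr, dc) I[(2 + dr):(ch - 1 + dr), (2 + dc):(cw - 1 + dc)]
  conv <- s(-1, -1) - 2 * s(-1, 0) + s(-1, 1) -
      2 * s(0, -1) + 4 * s(0, 0) - 2 * s(0, 1) +
          s(1, -1) - 2 * s(1, 0) + s(1, 1)
  sqrt(pi / 2) * sum(abs(conv)) / (6 * (cw - 2) * (ch - 2))
}

#' Frame-level QC status
#'
#' Applies the frame rules in a fixed order -- empty mask, roundness below
#' threshold, area below minimum, area above maximum -- and returns the first
#' failure, or \code{"pass"}.
#'
#' @param features one row of \code{\link{extractStudyFeatures}} output (or
#'   a list with \code{emptyMask}, \code{roundness}, \code{areaCm2}).
#' @param thresholds a \code{\link{qcThresholds}}.
#' @return one of \code{"pass"}, \code{"fail_roundness"},
#'   \code{"fail_area_low"}, \code{"fail_area_high"}, \code{"empty_mask"}.
#' @export
frameQC <- function(features, thresholds = qcThresholds()) {
  if (isTRUE(features$emptyMask) || is.na(features$areaCm2)) return("empty_mask")
  if (features$roundness < thresholds$roundnessMin) return("fail_roundness")
  if (features$areaCm2 < thresholds$areaMinCm2) return("fail_area_low")
  if (features$areaCm2 > thresholds$areaMaxCm2) return("fail_area_high")
  "pass"
}

#' Participant-level QC cascade
#'
#' Evaluates frame-level QC first, then the participant rules, then
#' covariate missingness:
#' \itemize{
#'   \item excluded from \emph{all} traits when more than
#'     \code{maxExcludedFraction} of frames fail frame QC, when no frame is
#'     retained, or when the mean absolute area difference between
#'     consecutive retained frames exceeds \code{maxMeanFrameDiffCm2};
#'   \item excluded from AAomax and AAodist (but \emph{not} AAomin) when any
#'     frame's noise sigma exceeds \code{sigmaMax} -- flow-void artefacts
#'     appear in the systolic phase, so the diastolic minimum is unaffected;
#'   \item excluded from AAomax and AAomin when BSA inputs (height/weight)
#'     are missing; excluded from AAodist when SBP or DBP is missing.
#' }
#'
#' @param features data.frame from \code{\link{extractStudyFeatures}}.
#' @param covariates named list with \code{sbp}, \code{dbp}, \code{height},
#'   \code{weight} (NA for missing).
#' @param thresholds a \code{\link{qcThresholds}}.
#' @return list of class \code{"participantQCReport"}: \code{frameStatus},
#'   \code{retainedFrames}, \code{nExcludedFrames}, \code{meanAbsFrameDiff},
#'   \code{maxSigma}, \code{includedFor} (named logical: AAomax, AAomin,
#'   AAodist), \code{exclusionReasons} (named list of character vectors).
#' @export
participantQC <- function(features, covariates, thresholds = qcThresholds()) {
  stopifnot(nrow(features) >= 1L)
  status <- vapply(seq_len(nrow(features)),
                   function(i) frameQC(features[i, ], thresholds), character(1))
  retained <- which(status == "pass")
  nExcl <- sum(status != "pass")
  areas <- features$areaCm2[retained]
  meanDiff <- if (length(areas) >= 2L) mean(abs(diff(areas))) else 0
  maxSigma <- suppressWarnings(max(features$noiseSigma, na.rm = TRUE))
  if (!is.finite(maxSigma)) maxSigma <- NA_real_

  reasons <- list(AAomax = character(), AAomin = character(),
                  AAodist = character())
  addAll <- function(reasons, r) lapply(reasons, function(x) c(x, r))
  if (length(retained) == 0L)
    reasons <- addAll(reasons, "no_retained_frames")
  if (nExcl > thresholds$maxExcludedFraction * nrow(features))
    reasons <- addAll(reasons, "excluded_frame_fraction")
  if (length(retained) > 0L && meanDiff > thresholds$maxMeanFrameDiffCm2)
    reasons <- addAll(reasons, "frame_to_frame_area_difference")
  if (is.finite(maxSigma) && maxSigma > thresholds$sigmaMax) {
    reasons$AAomax <- c(reasons$AAomax, "interpixel_variance")
    reasons$AAodist <- c(reasons$AAodist, "interpixel_variance")
  }
  bsaMissing <- is.null(covariates$height) || is.null(covariates$weight) ||
    is.na(covariates$height) || is.na(covariates$weight) ||
    covariates$height <= 0 || covariates$weight <= 0
  if (bsaMissing) {
    reasons$AAomax <- c(reasons$AAomax, "missing_bsa")
    reasons$AAomin <- c(reasons$AAomin, "missing_bsa")
  }
  bpMissing <- is.null(covariates$sbp) || is.null(covariates$dbp) ||
    is.na(covariates$sbp) || is.na(covariates$dbp)
  if (bpMissing)
    reasons$AAodist <- c(reasons$AAodist, "missing_blood_pressure")

  structure(list(
    frameStatus = status, retainedFrames = retained,
    nExcludedFrames = nExcl, meanAbsFrameDiff = meanDiff,
    maxSigma = maxSigma,
    includedFor = vapply(reasons, function(r) length(r) == 0L, logical(1)),
    exclusionReasons = reasons
  ), class = "participantQCReport")
}

#' Cohort exclusion table
#'
#' Tabulates, per trait, how many participants each exclusion reason removed
#' and how many remain -- the study-flowchart accounting. A participant can
#' contribute to several reasons; \code{included + excluded} (distinct
#' participants) equals the cohort size per trait.
#'
#' @param reports list of \code{\link{participantQC}} reports.
#' @return list: \code{counts} data.frame (trait, reason, n),
#'   \code{included} named vector, \code{nCohort}.
#' @export
cohortExclusionTable <- function(reports) {
  traits <- c("AAomax", "AAomin", "AAodist")
  counts <- do.call(rbind, lapply(traits, function(tr) {
    rs <- unlist(lapply(reports, function(r) unique(r$exclusionReasons[[tr]])))
    if (!length(rs)) return(NULL)
    tab <- table(rs)
    data.frame(trait = tr, reason = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  included <- vapply(traits, function(tr)
    sum(vapply(reports, function(r) r$includedFor[[tr]], logical(1))),
    integer(1))
  list(counts = counts, included = included, nCohort = length(reports))
}

#' @export
print.participantQCReport <- function(x, ...) {
  cat("Participant QC:", x$nExcludedFrames, "of", length(x$frameStatus),
      "frames excluded; mean |dArea| =", signif(x$meanAbsFrameDiff, 3),
      "cm^2; max sigma_n =", signif(x$maxSigma, 3), "\n")
  cat("  included for:",
      paste(names(x$includedFor)[x$includedFor], collapse = ", "), "\n")
  invisible(x)
}
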