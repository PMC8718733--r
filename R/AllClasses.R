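#' @import methods
NULL

#' CineStudy: one participant's cine acquisition
#'
#' Container for a single participant's ordered cine frames (one cardiac
#' cycle), the pixel spacing metadata needed to convert pixel measurements to
#' metric units, the covariates recorded at the imaging visit, and -- for
#' synthetic studies -- the generative ground truth.
#'
#' @slot frames numeric array (height x width x n_frames) of brightness
#'   values on a 0--255-like scale.
#' @slot pixelSpacing numeric length-2, mm per pixel along (row, column).
#' @slot participantId character scalar.
#' @slot covariates named list: \code{sbp}, \code{dbp} (mmHg), \code{height}
#'   (cm), \code{weight} (kg), \code{age} (years), \code{sex}
#'   (\code{"M"}/\code{"F"}). Any entry may be \code{NA}.
#' @slot groundTruth either \code{NULL} (real data) or a named list with
#'   \code{masks} (logical array matching \code{frames}), \code{areaCm2}
#'   (per-frame analytic lumen area, cm^2), \code{aaoMax}, \code{aaoMin}
#'   (cm^2), \code{distensibility} (10^-3 mmHg^-1), and
#'   \code{artefactFrames} (integer frame indices).
#'
#' @exportClass CineStudy
setClass("CineStudy",
  representation(
    frames = "array",
    pixelSpacing = "numeric",
    participantId = "character",
    covariates = "list",
    groundTruth = "ANY"
  )
)

setValidity("CineStudy", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a height x width x n_frames array")
  else if (d[3L] < 2L)
    msg <- c(msg, "a cine study needs at least 2 frames")
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (mm/pixel)")
  if (length(object@participantId) != 1L)
    msg <- c(msg, "participantId must be a single string")
  gt <- object@groundTruth
  if (!is.null(gt)) {
    if (!is.list(gt) || is.null(gt$masks) || is.null(gt$areaCm2))
      msg <- c(msg, "groundTruth must carry masks and areaCm2")
    else if (!identical(dim(gt$masks), d))
      msg <- c(msg, "groundTruth masks must match frame dimensions")
    else if (!isTRUE(all.equal(gt$aaoMax, max(gt$areaCm2))) ||
             !isTRUE(all.equal(gt$aaoMin, min(gt$areaCm2))))
      msg <- c(msg, "ground-truth AAomax/AAomin must be the extremes of areaCm2")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedInstrumentSet: aligned exposure/outcome effect pairs
#'
#' Result of harmonizing exposure and outcome summary statistics to a shared
#' effect-allele orientation. Retained instruments live in
#' \code{instruments}; variants dropped during harmonization or Steiger
#' filtering are kept in \code{removed} with a reason.
#'
#' @slot instruments data.frame with one row per retained variant: \code{snp},
#'   \code{betaExposure}, \code{seExposure}, \code{betaOutcome},
#'   \code{seOutcome}, \code{eaf}, \code{nExposure}, \code{nOutcome},
#'   \code{flipped} (logical), and, once filled by
#'   \code{\link{instrumentStrength}}, \code{r2Exposure}, \code{r2Outcome},
#'   \code{fStat}, \code{weakInstrument}, plus \code{steigerRemoved} after
#'   \code{\link{steigerFilter}}.
#' @slot removed data.frame (\code{snp}, \code{reason}).
#' @slot exposure,outcome character labels for reporting.
#'
#' @exportClass HarmonizedInstrumentSet
setClass("HarmonizedInstrumentSet",
  representation(
    instruments = "data.frame",
    removed = "data.frame",
    exposure = "character",
    outcome = "character"
  )
)

setValidity("HarmonizedInstrumentSet", function(object) {
  need <- c("snp", "betaExposure", "seExposure", "betaOutcome", "seOutcome",
            "eaf", "nExposure", "nOutcome")
  msg <- character()
  miss <- setdiff(need, names(object@instruments))
  if (length(miss))
    msg <- c(msg, paste("instruments lacks columns:", paste(miss, collapse = ", ")))
  else {
    ins <- object@instruments
    if (nrow(ins)) {
      if (any(ins$seExposure <= 0) || any(ins$seOutcome <= 0))
        msg <- c(msg, "standard errors must be positive")
      if (any(ins$eaf <= 0 | ins$eaf >= 1, na.rm = TRUE))
        msg <- c(msg, "eaf must lie strictly in (0, 1)")
      if ("fStat" %in% names(ins) && any(ins$fStat < 0, na.rm = TRUE))
        msg <- c(msg, "F statistics must be non-negative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' MRResult: one Mendelian randomization estimate
#'
#' A causal estimate from one MR estimator, together with its heterogeneity
#' statistics and (for MR-Egger) the intercept test and I2_GX. Slots that a
#' given estimator does not produce are \code{NA}.
#'
#' @slot method character label ("IVW-RE", "MR-Egger", "Wald ratio",
#'   "Weighted median", "Weighted mode").
#' @slot estimate,se,ciLower,ciUpper,p numeric; estimate on the scale of the
#'   outcome statistics (log odds per exposure SD for binary outcomes).
#' @slot k integer, number of instruments used.
#' @slot Q,QDf,QP numeric Cochran heterogeneity statistic, df and p.
#' @slot I2 numeric, \eqn{max(0, (Q - df)/Q)}.
#' @slot intercept,interceptSE,interceptP numeric, MR-Egger only.
#' @slot QPrime numeric, Egger residual heterogeneity (Q').
#' @slot I2GX numeric, Egger measurement-error diagnostic.
#'
#' @exportClass MRResult
setClass("MRResult",
  representation(
    method = "character",
    estimate = "numeric", se = "numeric",
    ciLower = "numeric", ciUpper = "numeric", p = "numeric",
    k = "integer",
    Q = "numeric", QDf = "numeric", QP = "numeric", I2 = "numeric",
    intercept = "numeric", interceptSE = "numeric", interceptP = "numeric",
    QPrime = "numeric", I2GX = "numeric"
  ),
  prototype(
    Q = NA_real_, QDf = NA_real_, QP = NA_real_, I2 = NA_real_,
    intercept = NA_real_, interceptSE = NA_real_, interceptP = NA_real_,
    QPrime = NA_real_, I2GX = NA_real_
  )
)

setValidity("MRResult", function(object) {
  msg <- character()
  if (is.finite(object@ciLower) && is.finite(object@ciUpper) &&
      (object@estimate < object@ciLower || object@estimate > object@ciUpper))
    msg <- c(msg, "confidence interval must contain the estimate")
  if (is.finite(object@Q) && object@Q < 0)
    msg <- c(msg, "Q must be non-negative")
  if (length(msg)) msg else TRUE
})
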