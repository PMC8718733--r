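#' @include AllClasses.R
NULL

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @export
setGeneric("removedVariants", function(x) standardGeneric("removedVariants"))
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))
#' @export
setGeneric("mrEstimate", function(x) standardGeneric("mrEstimate"))
#' @export
setGeneric("mrOddsRatio", function(x) standardGeneric("mrOddsRatio"))

#' Accessors for CineStudy
#'
#' @param x a \linkS4class{CineStudy}.
#' @return \code{frames}: the brightness array; \code{pixelSpacing}: mm/pixel
#'   pair; \code{covariates}: named list; \code{groundTruth}: list or NULL;
#'   \code{nFrames}: integer.
#' @name CineStudy-accessors
#' @aliases frames pixelSpacing participantId covariates groundTruth nFrames
NULL

setMethod("frames", "CineStudy", function(x) x@frames)
setMethod("pixelSpacing", "CineStudy", function(x) x@pixelSpacing)
setMethod("participantId", "CineStudy", function(x) x@participantId)
setMethod("covariates", "CineStudy", function(x) x@covariates)
setMethod("groundTruth", "CineStudy", function(x) x@groundTruth)
setMethod("nFrames", "CineStudy", function(x) dim(x@frames)[3L])

setMethod("show", "CineStudy", function(object) {
  d <- dim(object@frames)
  cat("CineStudy '", object@participantId, "': ", d[3L], " frames of ",
      d[1L], "x", d[2L], " px, spacing ",
      paste(signif(object@pixelSpacing, 3), collapse = " x "), " mm",
      if (!is.null(object@groundTruth)) " [with ground truth]", "\n", sep = "")
})

#' Accessors for HarmonizedInstrumentSet
#'
#' @param x a \linkS4class{HarmonizedInstrumentSet}.
#' @return \code{instruments}: data.frame of retained variants;
#'   \code{removedVariants}: data.frame of dropped variants with reasons;
#'   \code{nInstruments}: integer count of retained variants.
#' @name HarmonizedInstrumentSet-accessors
#' @aliases instruments removedVariants nInstruments
NULL

setMethod("instruments", "HarmonizedInstrumentSet", function(x) x@instruments)
setMethod("removedVariants", "HarmonizedInstrumentSet", function(x) x@removed)
setMethod("nInstruments", "HarmonizedInstrumentSet",
          function(x) nrow(x@instruments))

setMethod("show", "HarmonizedInstrumentSet", function(object) {
  cat("HarmonizedInstrumentSet: ", nrow(object@instruments),
      " instruments (", nrow(object@removed), " removed), exposure '",
      object@exposure, "' -> outcome '", object@outcome, "'\n", sep = "")
  if (nrow(object@removed)) {
    tab <- table(object@removed$reason)
    cat("  removed:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Accessors for MRResult
#'
#' @param x an \linkS4class{MRResult}.
#' @return \code{mrEstimate}: the causal estimate on the reporting scale;
#'   \code{mrOddsRatio}: \code{exp(estimate)} with its CI.
#' @name MRResult-accessors
#' @aliases mrEstimate mrOddsRatio
NULL

setMethod("mrEstimate", "MRResult", function(x) x@estimate)
setMethod("mrOddsRatio", "MRResult", function(x)
  c(or = exp(x@estimate), lower = exp(x@ciLower), upper = exp(x@ciUpper)))

setMethod("show", "MRResult", function(object) {
  cat(object@method, ": estimate ", signif(object@estimate, 4),
      " (SE ", signif(object@se, 3), "), 95% CI [",
      signif(object@ciLower, 4), ", ", signif(object@ciUpper, 4),
      "], p = ", signif(object@p, 3), ", k = ", object@k, "\n", sep = "")
  if (is.finite(object@Q))
    cat("  Q = ", signif(object@Q, 4), " (df ", object@QDf, ", p ",
        signif(object@QP, 3), "), I2 = ", signif(100 * object@I2, 3),
        "%\n", sep = "")
  if (is.finite(object@intercept))
    cat("  intercept = ", signif(object@intercept, 4), " (p ",
        signif(object@interceptP, 3), "), Q' = ", signif(object@QPrime, 4),
        ", I2_GX = ", signif(100 * object@I2GX, 3), "%\n", sep = "")
})
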