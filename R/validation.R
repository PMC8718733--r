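#' Sorensen-Dice similarity between two binary masks
#'
#' \eqn{DSC = 2 |X \cap Y| / (|X| + |Y|)}. Two empty masks agree perfectly on
#' absence: the coefficient is defined as 1 and flagged through the
#' \code{"bothEmpty"} attribute so callers can exclude such frames.
#'
#' @param x,y binary matrices of identical shape.
#' @return Dice coefficient in [0, 1].
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' dice(a, b)  # overlap 1 of 2+2 -> 0.5
#' @export
dice <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("mask shapes differ")
  xs <- sum(x != 0); ys <- sum(y != 0)
  if (xs + ys == 0) return(structure(1, bothEmpty = TRUE))
  2 * sum(x != 0 & y != 0) / (xs + ys)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measure, absolute-agreement ICC from the two-way random-effects
#' ANOVA decomposition -- the standard form for method comparison, where
#' systematic offsets between raters count against agreement. The 95\%
#' interval follows the F-based construction for ICC(A,1). A consistency
#' ICC, which ignores rater offsets, is available via \code{type}.
#'
#' @param ratings numeric items x raters matrix, complete, >= 5 items and
#'   >= 2 raters.
#' @param type \code{"agreement"} (default) or \code{"consistency"}.
#' @param conf confidence level (default 0.95).
#' @return list: \code{icc}, \code{lower}, \code{upper}, \code{n}, \code{k},
#'   plus the mean squares \code{MSR}, \code{MSC}, \code{MSE}.
#' @export
iccTwoWayRandom <- function(ratings, type = c("agreement", "consistency"),
                            conf = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L) stop("need >= 5 items and >= 2 raters")
  grand <- mean(ratings)
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  SSR <- k * sum((rowM - grand)^2)
  SSC <- n * sum((colM - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST <= 0) stop("zero total variance: ICC undefined")
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fo <- MSR / MSE
    Fl <- Fo / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    Fu <- Fo * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (Fl - 1) / (Fl + k - 1)
    upper <- (Fu - 1) / (Fu + k - 1)
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    # Satterthwaite df for the A,1 interval
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    Fl <- qf(1 - alpha / 2, n - 1, v)
    Fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - Fl * MSE) /
      (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (Fu * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  }
  list(icc = icc, lower = lower, upper = upper, n = n, k = k,
       MSR = MSR, MSC = MSC, MSE = MSE, type = type)
}

#' Validation-set accounting
#'
#' Book-keeping for a manual-contour validation set: a number of studies
#' with a fixed number of sampled frames each, minus studies dropped whole
#' (unusable image quality) and single images dropped from otherwise
#' retained studies.
#'
#' @param nStudies studies selected.
#' @param framesPerStudy frames sampled per study.
#' @param excludedStudies studies removed entirely.
#' @param excludedImages additional single images removed.
#' @return list: \code{images}, \code{studies} retained.
#' @examples
#' validationSetAccounting(50, 10, 6, 1)  # 439 images from 44 studies
#' @export
validationSetAccounting <- function(nStudies, framesPerStudy,
                                    excludedStudies = 0L,
                                    excludedImages = 0L) {
  stopifnot(excludedStudies <= nStudies)
  studies <- nStudies - excludedStudies
  images <- studies * framesPerStudy - excludedImages
  list(images = as.integer(images), studies = as.integer(studies))
}
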