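mrVectors <- function(x) {
  if (is(x, "HarmonizedInstrumentSet")) x <- x@instruments
  list(bx = x$betaExposure, sx = x$seExposure,
       by = x$betaOutcome, sy = x$seOutcome)
}

mrResult <- function(method, estimate, se, p = NULL, k, ...) {
  estimate <- unname(estimate); se <- unname(se)
  if (is.null(p)) p <- 2 * pnorm(-abs(estimate / se))
  z <- qnorm(0.975)
  new("MRResult", method = method, estimate = estimate, se = se,
      ciLower = estimate - z * se, ciUpper = estimate + z * se,
      p = p, k = as.integer(k), ...)
}

#' Wald ratio for a single instrument
#'
#' \eqn{\theta = \beta_Y / \beta_X} with the first-order standard error
#' \eqn{SE = se_Y / |\beta_X|}.
#'
#' @param bx,sx exposure effect and SE. @param by,sy outcome effect and SE.
#' @return an \linkS4class{MRResult}.
#' @examples
#' mrEstimate(waldRatio(0.1, 0.01, 0.05, 0.01))  # 0.5
#' @export
waldRatio <- function(bx, sx, by, sy) {
  if (bx == 0) stop("Wald ratio undefined for a zero exposure effect")
  mrResult("Wald ratio", by / bx, sy / abs(bx), k = 1L)
}

#' Inverse-variance-weighted MR with multiplicative random effects
#'
#' Zero-intercept regression of the outcome effects on the exposure effects
#' with weights \eqn{1/se_Y^2}. Heterogeneity beyond sampling error inflates
#' the SE multiplicatively by \eqn{\sqrt{\max(1, Q/(k-1))}} (never deflates
#' it). Cochran's Q and \eqn{I^2 = \max(0, (Q - df)/Q)} are attached. With a
#' single instrument the estimate equals the Wald ratio.
#'
#' @param x a \linkS4class{HarmonizedInstrumentSet} or a data.frame with
#'   betaExposure/seExposure/betaOutcome/seOutcome columns.
#' @return an \linkS4class{MRResult} (method "IVW-RE").
#' @export
mrIVW <- function(x) {
  v <- mrVectors(x)
  k <- length(v$bx)
  if (k < 1L) stop("no instruments")
  w <- 1 / v$sy^2
  est <- sum(w * v$bx * v$by) / sum(w * v$bx^2)
  seFixed <- 1 / sqrt(sum(w * v$bx^2))
  Q <- sum(w * (v$by - est * v$bx)^2)
  if (k == 1L)
    return(mrResult("IVW-RE", est, seFixed, k = 1L, Q = 0, QDf = 0,
                    QP = NA_real_, I2 = NA_real_))
  phi <- max(1, Q / (k - 1))
  mrResult("IVW-RE", est, seFixed * sqrt(phi), k = k,
           Q = Q, QDf = k - 1, QP = pchisq(Q, k - 1, lower.tail = FALSE),
           I2 = max(0, (Q - (k - 1)) / Q))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a \emph{free}
#' intercept capturing directional pleiotropy; the slope is the causal
#' estimate. Variants are first oriented so every exposure effect is
#' non-negative (Egger is not invariant to allele orientation). SEs use
#' multiplicative random effects floored at 1 (dispersion
#' \eqn{\max(1, Q'/(k-2))}). Attaches the Egger heterogeneity Q', and
#' \eqn{I^2_{GX}} -- the precision-weighted dispersion of the exposure
#' effects, with values above 95\% indicating low regression-dilution risk.
#'
#' @param x instruments as in \code{\link{mrIVW}}; needs k >= 3.
#' @return an \linkS4class{MRResult} (method "MR-Egger") with intercept
#'   slots filled.
#' @export
mrEgger <- function(x) {
  v <- mrVectors(x)
  k <- length(v$bx)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments")
  s <- ifelse(v$bx < 0, -1, 1)
  bx <- v$bx * s; by <- v$by * s
  w <- 1 / v$sy^2
  X <- cbind(1, bx)
  XtW <- t(X * w)
  XtWXinv <- solve(XtW %*% X)
  coef <- unname(drop(XtWXinv %*% (XtW %*% by)))
  res <- by - drop(X %*% coef)
  Qp <- sum(w * res^2)
  phi <- max(1, Qp / (k - 2))
  ses <- unname(sqrt(diag(XtWXinv) * phi))
  # precision-weighted dispersion of the exposure effects
  wx <- 1 / v$sx^2
  bxBar <- sum(wx * bx) / sum(wx)
  Qgx <- sum(wx * (bx - bxBar)^2)
  i2gx <- max(0, (Qgx - (k - 1)) / Qgx)
  r <- mrResult("MR-Egger", coef[2L], ses[2L], k = k,
                Q = Qp, QDf = k - 2,
                QP = pchisq(Qp, k - 2, lower.tail = FALSE),
                I2 = max(0, (Qp - (k - 2)) / Qp),
                intercept = coef[1L], interceptSE = ses[1L],
                interceptP = 2 * pnorm(-abs(coef[1L] / ses[1L])),
                QPrime = Qp, I2GX = i2gx)
  r
}

#' Ruecker model selection between IVW-RE and MR-Egger
#'
#' IVW-RE is the default causal model. The analysis switches to MR-Egger
#' only when both conditions for unbalanced horizontal pleiotropy hold: the
#' heterogeneity drop Q - Q' is significant against chi-square(1) at 0.05,
#' \emph{and} the Egger intercept differs from zero at 0.05. Evidence for at
#' least balanced pleiotropy (significant Q with I^2 > 25\%) is reported
#' alongside; both fits are always returned.
#'
#' @param ivw result of \code{\link{mrIVW}}.
#' @param egger result of \code{\link{mrEgger}}.
#' @param alpha test level (default 0.05).
#' @return list: \code{selected} ("IVW-RE" or "MR-Egger"), \code{result}
#'   (the selected \linkS4class{MRResult}), \code{ivw}, \code{egger},
#'   \code{QDiff}, \code{QDiffP}, \code{balancedPleiotropy} (logical).
#' @export
ruckerSelect <- function(ivw, egger, alpha = 0.05) {
  qdiff <- max(0, ivw@Q - egger@QPrime)
  qdiffP <- pchisq(qdiff, df = 1, lower.tail = FALSE)
  useEgger <- qdiffP < alpha && is.finite(egger@interceptP) &&
    egger@interceptP < alpha
  balanced <- is.finite(ivw@QP) && ivw@QP < alpha && ivw@I2 > 0.25
  list(selected = if (useEgger) "MR-Egger" else "IVW-RE",
       result = if (useEgger) egger else ivw,
       ivw = ivw, egger = egger, QDiff = qdiff, QDiffP = qdiffP,
       balancedPleiotropy = balanced)
}

#' Weighted median MR estimator
#'
#' Median of the per-variant Wald ratios under inverse-variance weights,
#' with linear interpolation at cumulative weight one half; consistent when
#' the majority of the weight lies on valid instruments. The SE comes from a
#' parametric bootstrap (effects resampled from their reported SEs) with a
#' fixed seed.
#'
#' @param x instruments as in \code{\link{mrIVW}}; needs k >= 3.
#' @param bootstrapReps bootstrap replications (default 1000).
#' @param seed bootstrap seed (default 1).
#' @return an \linkS4class{MRResult} (method "Weighted median").
#' @export
mrWeightedMedian <- function(x, bootstrapReps = 1000L, seed = 1L) {
  v <- mrVectors(x)
  k <- length(v$bx)
  if (k < 3L) stop("weighted median needs at least 3 instruments")
  est <- weightedMedianCore(v$by / v$bx, v$bx^2 / v$sy^2)
  se <- ratioBootstrapSE(v, function(r, w) weightedMedianCore(r, w),
                         bootstrapReps, seed)
  mrResult("Weighted median", est, se, k = k)
}

weightedMedianCore <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1L] >= 0.5) return(ratio[1L])
  if (p[length(p)] <= 0.5) return(ratio[length(p)])
  stats::approx(p, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted mode MR estimator
#'
#' Mode of the smoothed, weighted empirical density of the Wald ratios
#' (normal kernel; bandwidth = \code{bandwidthFactor} times the modified
#' Silverman rule on the ratio spread); consistent when the largest group of
#' instruments sharing an effect -- a plurality -- is valid. Bootstrap SE
#' with fixed seed, as for the weighted median.
#'
#' @inheritParams mrWeightedMedian
#' @param bandwidthFactor multiplier on the default bandwidth (default 1).
#' @return an \linkS4class{MRResult} (method "Weighted mode").
#' @export
mrWeightedMode <- function(x, bandwidthFactor = 1, bootstrapReps = 1000L,
                           seed = 1L) {
  v <- mrVectors(x)
  k <- length(v$bx)
  if (k < 3L) stop("weighted mode needs at least 3 instruments")
  est <- weightedModeCore(v$by / v$bx, v$bx^2 / v$sy^2, bandwidthFactor)
  se <- ratioBootstrapSE(v, function(r, w) weightedModeCore(r, w, bandwidthFactor),
                         bootstrapReps, seed)
  mrResult("Weighted mode", est, se, k = k)
}

weightedModeCore <- function(ratio, w, bandwidthFactor = 1) {
  spread <- min(sd(ratio), mad(ratio))
  if (!is.finite(spread) || spread == 0) spread <- sd(ratio)
  if (!is.finite(spread) || spread == 0)
    return(sum(w * ratio) / sum(w))      # all ratios identical
  h <- bandwidthFactor * 0.9 * spread * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512L)
  dens <- vapply(grid, function(g)
    sum(w * dnorm((g - ratio) / h)), numeric(1))
  grid[which.max(dens)]
}

ratioBootstrapSE <- function(v, estimator, reps, seed) {
  old <- .Random.seed_exists(); set.seed(as.integer(seed))
  on.exit(.Random.seed_restore(old), add = TRUE)
  k <- length(v$bx)
  ests <- vapply(seq_len(reps), function(i) {
    bx <- rnorm(k, v$bx, v$sx)
    by <- rnorm(k, v$by, v$sy)
    bx[bx == 0] <- 1e-12
    estimator(by / bx, bx^2 / v$sy^2)
  }, numeric(1))
  sd(ests)
}

#' Run the full MR battery for one exposure-outcome pair
#'
#' Harmonized instruments go through strength annotation, optional Steiger
#' filtering, IVW-RE and (k >= 3) MR-Egger with Ruecker model selection, and
#' the weighted median and mode sensitivity estimators.
#'
#' @param hset a \linkS4class{HarmonizedInstrumentSet}.
#' @param steiger apply Steiger filtering (default TRUE).
#' @param outcomeType passed to \code{\link{instrumentStrength}}.
#' @param bootstrapReps,seed bootstrap settings for median/mode.
#' @return list: \code{set} (annotated/filtered set), \code{ivw},
#'   \code{egger} (or NULL), \code{rucker} (or NULL), \code{median},
#'   \code{mode} (or NULL), \code{selectedModel}, \code{main} (the selected
#'   \linkS4class{MRResult}).
#' @export
mrAnalyze <- function(hset, steiger = TRUE,
                      outcomeType = c("binary", "continuous"),
                      bootstrapReps = 1000L, seed = 1L) {
  outcomeType <- match.arg(outcomeType)
  hset <- instrumentStrength(hset, outcomeType = outcomeType)
  if (steiger) hset <- steigerFilter(hset)
  k <- nInstruments(hset)
  if (k < 1L) stop("no instruments survive harmonization/filtering")
  ivw <- mrIVW(hset)
  egger <- if (k >= 3L) mrEgger(hset) else NULL
  rucker <- if (!is.null(egger)) ruckerSelect(ivw, egger) else NULL
  med <- if (k >= 3L) mrWeightedMedian(hset, bootstrapReps, seed) else NULL
  mode <- if (k >= 3L) mrWeightedMode(hset, 1, bootstrapReps, seed) else NULL
  main <- if (!is.null(rucker)) rucker$result else ivw
  list(set = hset, ivw = ivw, egger = egger, rucker = rucker,
       median = med, mode = mode,
       selectedModel = if (!is.null(rucker)) rucker$selected else "IVW-RE",
       main = main)
}

#' Decision table across exposure-outcome pairs
#'
#' Rows are (exposure, outcome, method); the main model's p-value is tiered
#' against the Bonferroni-corrected significance level
#' (\code{alpha / nOutcomes}, default 0.05/10 = 0.005) and the suggestive
#' level 0.05. Odds ratios are the exponentiated estimates (binary
#' outcomes).
#'
#' @param analyses named list of \code{\link{mrAnalyze}} results; names are
#'   "exposure|outcome" pairs (or supply \code{exposures}/\code{outcomes}).
#' @param nOutcomes Bonferroni denominator (default 10).
#' @param alpha family-wise level (default 0.05).
#' @param instrumentPThreshold instrument inclusion threshold to record
#'   (default 5e-8; the relaxed option is 1e-6).
#' @return data.frame: exposure, outcome, method, estimate, se, or, orLower,
#'   orUpper, p, k, Q, QP, I2, intercept, interceptP, selectedModel, tier
#'   (the tier is set on the selected main model's row).
#' @export
mrReport <- function(analyses, nOutcomes = 10L, alpha = 0.05,
                     instrumentPThreshold = 5e-8) {
  bonf <- alpha / nOutcomes
  rows <- lapply(names(analyses), function(nm) {
    an <- analyses[[nm]]
    pair <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    exposure <- pair[1L]; outcome <- if (length(pair) > 1L) pair[2L] else ""
    results <- Filter(Negate(is.null),
                      list(an$ivw, an$egger, an$median, an$mode))
    do.call(rbind, lapply(results, function(r) {
      isMain <- identical(r@method, an$selectedModel)
      data.frame(
        exposure = exposure, outcome = outcome, method = r@method,
        estimate = r@estimate, se = r@se,
        or = exp(r@estimate), orLower = exp(r@ciLower),
        orUpper = exp(r@ciUpper), p = r@p, k = r@k,
        Q = r@Q, QP = r@QP, I2 = r@I2,
        intercept = r@intercept, interceptP = r@interceptP,
        selectedModel = an$selectedModel,
        tier = if (!isMain) "" else significanceTier(r@p, bonf, alpha),
        instrumentPThreshold = instrumentPThreshold,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significance tier for a main MR result
#'
#' @param p p-value.
#' @param significant Bonferroni-corrected level (default 0.005).
#' @param suggestive nominal level (default 0.05).
#' @return "significant", "suggestive" or "null".
#' @export
significanceTier <- function(p, significant = 0.005, suggestive = 0.05) {
  if (is.na(p)) return("null")
  if (p < significant) "significant" else if (p < suggestive) "suggestive"
  else "null"
}
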