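#' Configuration for a synthetic cine cohort
#'
#' Bundles every parameter of the synthetic cine generator. Defaults emulate
#' the population the phenotype reference values describe: diastolic lumen
#' area averaging 7.2 cm^2, systolic 8.1 cm^2, pulse pressure averaging
#' ~54.7 mmHg, body surface area ~1.9 m^2, and a loop of 100 frames per
#' cardiac cycle.
#'
#' @param nParticipants number of participants to generate.
#' @param nFrames frames per cine loop (>= 2; default 100, one cardiac cycle).
#' @param imageSize integer (height, width) in pixels.
#' @param pixelSpacing positive (row, column) spacing in mm/pixel; unequal
#'   values give anisotropic images.
#' @param areaDiastoleRange cm^2 range the per-participant diastolic lumen
#'   area is drawn from (uniform).
#' @param areaSystoleRange cm^2 range for the systolic area; draws below the
#'   participant's diastolic area are rejected and redrawn so systole >=
#'   diastole always holds.
#' @param artefactProbability per-frame probability that a systolic-phase
#'   frame carries a flow-void artefact.
#' @param artefactAmplitude half-width of the zero-mean uniform brightness
#'   noise added inside the lumen of artefact frames (0--255 scale).
#' @param noiseSigma SD of the i.i.d. Gaussian acquisition noise added to
#'   every pixel (0--255 scale).
#' @param bpDistribution list \code{sbpMean, sbpSD, dbpMean, dbpSD} (mmHg).
#' @param anthropometry list \code{heightMean, heightSD} (cm),
#'   \code{weightMean, weightSD} (kg).
#' @param ageRange years, uniform draw.
#' @param seed single integer; all randomness derives from it.
#'
#' @return a list of class \code{"cohortConfig"}.
#' @examples
#' cfg <- cohortConfig(nParticipants = 2, nFrames = 10, seed = 1)
#' @export
cohortConfig <- function(nParticipants,
                         nFrames = 100L,
                         imageSize = c(192L, 192L),
                         pixelSpacing = c(0.6, 0.6),
                         areaDiastoleRange = c(6.2, 8.2),
                         areaSystoleRange = c(7.1, 9.1),
                         artefactProbability = 0.1,
                         artefactAmplitude = 40,
                         noiseSigma = 2.5,
                         bpDistribution = list(sbpMean = 133.6, sbpSD = 17.8,
                                               dbpMean = 78.9, dbpSD = 8.5),
                         anthropometry = list(heightMean = 170, heightSD = 10,
                                              weightMean = 78, weightSD = 15),
                         ageRange = c(45, 80),
                         seed = 1L) {
  if (nParticipants < 1L) stop("nParticipants must be >= 1")
  if (nFrames < 2L) stop("nFrames must be >= 2")
  if (any(imageSize < 16L)) stop("imageSize too small")
  if (any(pixelSpacing <= 0)) stop("pixelSpacing must be positive")
  if (diff(areaDiastoleRange) < 0 || diff(areaSystoleRange) < 0)
    stop("area ranges must be increasing")
  if (areaSystoleRange[2L] < areaDiastoleRange[1L])
    stop("systolic range lies entirely below the diastolic range")
  if (artefactProbability < 0 || artefactProbability > 1)
    stop("artefactProbability must be in [0, 1]")
  if (artefactAmplitude < 0 || noiseSigma < 0)
    stop("noise parameters must be non-negative")
  structure(list(
    nParticipants = as.integer(nParticipants), nFrames = as.integer(nFrames),
    imageSize = as.integer(imageSize), pixelSpacing = as.numeric(pixelSpacing),
    areaDiastoleRange = areaDiastoleRange, areaSystoleRange = areaSystoleRange,
    artefactProbability = artefactProbability,
    artefactAmplitude = artefactAmplitude, noiseSigma = noiseSigma,
    bpDistribution = bpDistribution, anthropometry = anthropometry,
    ageRange = ageRange, seed = as.integer(seed)
  ), class = "cohortConfig")
}

# Deterministic 31-bit stream seed for (global seed, participant id), so
# studies can be generated independently and in any order.
participantSeed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(id)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Raised-cosine systolic pulse occupying the first 40% of the cycle:
# 0 at end-diastole, 1 at the systolic peak (t = 0.2), back to 0 by t = 0.4.
systolicPulse <- function(t) {
  p <- numeric(length(t))
  w <- t < 0.4
  p[w] <- 0.5 * (1 - cos(2 * pi * t[w] / 0.4))
  p
}

#' Generate one synthetic cine study with ground truth
#'
#' Renders \code{nFrames} frames of a bright elliptical lumen on a darker,
#' smoothly textured background. The lumen area follows a raised-cosine
#' systolic pulse from the participant's diastolic to systolic area and back
#' within one cycle. Flow-void artefacts -- localized high-frequency
#' brightness noise inside the lumen -- are drawn independently for frames in
#' the systolic window. Output is bit-identical for the same (seed, id).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param participantId identifier string; combined with the config seed to
#'   derive this participant's random stream.
#' @return a \linkS4class{CineStudy} whose \code{groundTruth} carries the
#'   per-frame lumen masks, the analytic area schedule (cm^2), true AAomax /
#'   AAomin, true distensibility (10^-3 mmHg^-1) and artefact frame indices.
#' @examples
#' st <- generateCineStudy(cohortConfig(1, nFrames = 8, seed = 7), "p1")
#' nFrames(st)
#' @export
generateCineStudy <- function(config, participantId) {
  stopifnot(inherits(config, "cohortConfig"))
  H <- config$imageSize[1L]; W <- config$imageSize[2L]
  sx <- config$pixelSpacing[1L]; sy <- config$pixelSpacing[2L]
  nf <- config$nFrames

  rs <- participantSeed(config$seed, participantId)
  old <- .Random.seed_exists()
  set.seed(rs)
  on.exit(.Random.seed_restore(old), add = TRUE)

  # covariates
  bp <- config$bpDistribution; an <- config$anthropometry
  repeat {
    sbp <- rnorm(1, bp$sbpMean, bp$sbpSD)
    dbp <- rnorm(1, bp$dbpMean, bp$dbpSD)
    if (sbp - dbp >= 5) break
  }
  height <- max(120, rnorm(1, an$heightMean, an$heightSD))
  weight <- max(35, rnorm(1, an$weightMean, an$weightSD))
  age <- runif(1, config$ageRange[1L], config$ageRange[2L])
  sex <- if (runif(1) < 0.5) "F" else "M"
  pp <- sbp - dbp

  # per-participant geometry
  areaDia <- runif(1, config$areaDiastoleRange[1L], config$areaDiastoleRange[2L])
  repeat {
    areaSys <- runif(1, config$areaSystoleRange[1L], config$areaSystoleRange[2L])
    if (areaSys >= areaDia) break
  }
  aspect <- runif(1, 0.94, 1.0)       # near-circular lumen
  phi <- runif(1, 0, pi)
  cy <- H / 2 + 0.5 + runif(1, -3, 3) # row centre (pixel-centre coords, 1-based)
  cx <- W / 2 + 0.5 + runif(1, -3, 3)

  tFrac <- (seq_len(nf) - 1) / nf
  areaCm2 <- areaDia + (areaSys - areaDia) * systolicPulse(tFrac)
  systolicWindow <- which(tFrac < 0.4)
  artefactFrames <- systolicWindow[
    runif(length(systolicWindow)) < config$artefactProbability]

  # smooth low-frequency background texture (does not excite the noise kernel)
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  texture <- 8 * sin(2 * pi * rr / 47 + runif(1, 0, 2 * pi)) +
             8 * sin(2 * pi * cc / 61 + runif(1, 0, 2 * pi))
  bgLevel <- 60; lumenLevel <- 200

  cphi <- cos(phi); sphi <- sin(phi)
  frames <- array(0, dim = c(H, W, nf))
  masks <- array(FALSE, dim = c(H, W, nf))
  for (f in seq_len(nf)) {
    areaPx <- areaCm2[f] * 100 / (sx * sy)
    a <- sqrt(areaPx / (pi * aspect))   # semi-major, px
    b <- aspect * a
    u <- (rr - cy) * cphi + (cc - cx) * sphi
    v <- -(rr - cy) * sphi + (cc - cx) * cphi
    rho <- sqrt((u / a)^2 + (v / b)^2)  # 1 on the ellipse boundary
    mask <- rho <= 1
    img <- bgLevel + texture +
      (lumenLevel - bgLevel) * stats::plogis((1 - rho) * a / 0.5)
    if (f %in% artefactFrames)
      img[mask] <- img[mask] +
        runif(sum(mask), -config$artefactAmplitude, config$artefactAmplitude)
    img <- img + rnorm(H * W, 0, config$noiseSigma)
    frames[, , f] <- pmin(255, pmax(0, img))
    masks[, , f] <- mask
  }

  gt <- list(
    masks = masks,
    areaCm2 = areaCm2,
    aaoMax = max(areaCm2),
    aaoMin = min(areaCm2),
    distensibility = 1000 * (max(areaCm2) - min(areaCm2)) / (min(areaCm2) * pp),
    artefactFrames = artefactFrames
  )
  new("CineStudy",
      frames = frames, pixelSpacing = c(sx, sy),
      participantId = as.character(participantId),
      covariates = list(sbp = sbp, dbp = dbp, pp = pp, height = height,
                        weight = weight, age = age, sex = sex),
      groundTruth = gt)
}

#' Generate a synthetic cohort
#'
#' Calls \code{\link{generateCineStudy}} for \code{nParticipants} ids
#' ("P001", "P002", ...) and assembles the covariate table.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{studies} (list of \linkS4class{CineStudy}) and
#'   \code{covariates} (data.frame: id, sbp, dbp, pp, height, weight, age,
#'   sex).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  ids <- sprintf("P%03d", seq_len(config$nParticipants))
  studies <- lapply(ids, function(id) generateCineStudy(config, id))
  names(studies) <- ids
  cov <- do.call(rbind, lapply(studies, function(s) {
    cv <- covariates(s)
    data.frame(id = participantId(s), sbp = cv$sbp, dbp = cv$dbp, pp = cv$pp,
               height = cv$height, weight = cv$weight, age = cv$age,
               sex = cv$sex, stringsAsFactors = FALSE)
  }))
  rownames(cov) <- NULL
  list(studies = studies, covariates = cov)
}

# save/restore the global RNG state around seeded generation
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
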