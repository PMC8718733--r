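#' Extract the outer contour of a single-component mask
#'
#' Traces the 8-connected outer border of the (single) foreground component
#' and measures it in pixel space: polygon area by the shoelace formula on
#' the border polygon and perimeter as the polygon arc length, diagonal
#' steps counting sqrt(2). Coordinates are (row, col), 0-based, origin
#' top-left, pixel centres at integers. The raw foreground pixel count is
#' kept alongside as a diagnostic: for small structures the border polygon
#' through pixel centres sits about half a pixel inside the true boundary,
#' so its shoelace area runs below the pixel count.
#'
#' @param mask integer/logical matrix with exactly one foreground component
#'   (enforced upstream by \code{\link{selectPrimaryComponent}}).
#' @return list of class \code{"aaoContour"}: \code{vertices} (n x 2,
#'   (row, col) 0-based), \code{areaPx} (shoelace), \code{perimeterPx},
#'   \code{pixelCount}, \code{borderTouching} (logical), \code{empty}
#'   (logical; TRUE for an empty or degenerate mask).
#' @examples
#' m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
#' ct <- extractContour(m)
#' c(ct$areaPx, ct$perimeterPx)  # 81, 36
#' @export
extractContour <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  emptyOut <- structure(list(vertices = matrix(numeric(0), 0, 2),
                             areaPx = 0, perimeterPx = 0,
                             pixelCount = sum(m), borderTouching = FALSE,
                             empty = TRUE), class = "aaoContour")
  if (sum(m) < 3L) return(emptyOut)
  oc <- EBImage::ocontour(m)
  if (!length(oc)) return(emptyOut)
  v <- oc[[1L]]                       # (row, col), 0-based pixel centres
  if (nrow(v) < 3L) return(emptyOut)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  areaPx <- abs(sum(x * yn - xn * y)) / 2
  perimeterPx <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  if (areaPx <= 0) return(emptyOut)
  borderTouching <- any(v[, 1L] %in% c(0L, nrow(m) - 1L)) ||
                    any(v[, 2L] %in% c(0L, ncol(m) - 1L))
  structure(list(vertices = v, areaPx = areaPx, perimeterPx = perimeterPx,
                 pixelCount = sum(m), borderTouching = borderTouching,
                 empty = FALSE), class = "aaoContour")
}

#' Smallest bounding ellipse of a contour
#'
#' Default method is the minimum-volume enclosing ellipse (MVEE) of the
#' contour vertices by Khachiyan's barycentric coordinate-descent, iterated
#' to the given tolerance; every vertex is inside the returned ellipse to
#' within a scaled 1e-6 tolerance. A direct least-squares conic fit
#' (\code{method = "lsq"}) is available as an alternative reading of a
#' "smallest bounding ellipse", but is not guaranteed to enclose.
#'
#' @param contour an \code{"aaoContour"} or an n x 2 vertex matrix.
#' @param tol Khachiyan convergence tolerance (default 1e-7).
#' @param method \code{"mvee"} (default) or \code{"lsq"}.
#' @return list: \code{centre} (row, col), \code{axisMajorPx},
#'   \code{axisMinorPx} (full axis lengths, px), \code{orientation}
#'   (radians, major axis vs row axis), \code{shape} (2 x 2 matrix A with
#'   the ellipse \eqn{(z-c)' A (z-c) \le 1}).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' e <- minBoundingEllipse(cbind(10 * cos(th), 10 * sin(th)))
#' e$axisMajorPx  # ~20
#' @export
minBoundingEllipse <- function(contour, tol = 1e-7, method = c("mvee", "lsq")) {
  method <- match.arg(method)
  P <- if (inherits(contour, "aaoContour")) contour$vertices else as.matrix(contour)
  if (nrow(P) < 3L) stop("need at least 3 vertices")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1)) stop("degenerate geometry: collinear vertices")
  if (method == "lsq") return(fitEllipseLSQ(P))
  P <- P[grDevices::chull(P), , drop = FALSE]  # MVEE depends on hull points only
  N <- nrow(P); d <- 2L
  Q <- t(cbind(P, 1))
  u <- rep(1 / N, N)
  # Khachiyan barycentric ascent with drop steps (faster convergence at the
  # same optimality tolerance)
  for (i in seq_len(50000L)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    jp <- which.max(M)
    epsPlus <- M[jp] / (d + 1) - 1
    pos <- which(u > 0)
    jm <- pos[which.min(M[pos])]
    epsMinus <- 1 - M[jm] / (d + 1)
    if (epsPlus < tol) break
    if (epsPlus >= epsMinus) {
      step <- (M[jp] - d - 1) / ((d + 1) * (M[jp] - 1))
      u <- u * (1 - step); u[jp] <- u[jp] + step
    } else {
      step <- max((M[jm] - d - 1) / ((d + 1) * (M[jm] - 1)),
                  -u[jm] / (1 - u[jm]))
      u <- u * (1 - step); u[jm] <- u[jm] + step
    }
    u <- pmax(u, 0); u <- u / sum(u)
  }
  c0 <- unname(drop(t(P) %*% u))
  A <- solve(crossprod(sqrt(u) * P) - tcrossprod(c0)) / d
  # guarantee containment: inflate by the worst vertex's quadratic form
  Z <- sweep(P, 2, c0)
  qf <- rowSums((Z %*% A) * Z)
  A <- A / max(max(qf), 1)
  e <- eigen(A, symmetric = TRUE)
  semi <- 1 / sqrt(e$values)          # decreasing e$values -> increasing semi
  major <- which.max(semi)
  list(centre = c0,
       axisMajorPx = 2 * max(semi), axisMinorPx = 2 * min(semi),
       orientation = atan2(e$vectors[2L, major], e$vectors[1L, major]) %% pi,
       shape = A)
}

# Direct least-squares ellipse fit (algebraic conic, ellipse-constrained).
fitEllipseLSQ <- function(P) {
  x <- P[, 1L]; y <- P[, 2L]
  mx <- mean(x); my <- mean(y); x <- x - mx; y <- y - my
  D1 <- cbind(x^2, x * y, y^2); D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  e <- eigen(M)
  ev <- Re(e$vectors)
  cond <- 4 * ev[1L, ] * ev[3L, ] - ev[2L, ]^2
  a1 <- ev[, which(cond > 0)[1L]]
  par <- unname(c(a1, drop(Tm %*% a1)))  # A B C D E F (centred coords)
  A <- par[1L]; B <- par[2L]; C <- par[3L]
  D <- par[4L]; E <- par[5L]; Fc <- par[6L]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s <- sqrt((A - C)^2 + B^2)
  semi1 <- sqrt(num / (den * (s - (A + C))))
  semi2 <- sqrt(num / (den * (-s - (A + C))))
  ang <- atan2(C - A - s, B)
  semi <- sort(c(semi1, semi2), decreasing = TRUE)
  shape <- diag(1 / semi^2)
  R <- cbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
  list(centre = c(cx + mx, cy + my),
       axisMajorPx = 2 * semi[1L], axisMinorPx = 2 * semi[2L],
       orientation = ang %% pi, shape = R %*% shape %*% t(R))
}

#' Convert pixel-space contour and ellipse measurements to metric units
#'
#' Area converts with the exact product of the two spacings
#' (\code{areaCm2 = areaPx * sx * sy / 100}). Lengths (perimeter, ellipse
#' axes, diameter) convert with the common spacing when the image is
#' isotropic; with anisotropy above 1\% the mean spacing is used and a
#' warning is emitted, since a single length scale no longer exists.
#'
#' @param contour an \code{"aaoContour"}.
#' @param ellipse result of \code{\link{minBoundingEllipse}} (may be NULL
#'   for an empty contour).
#' @param spacing (sx, sy) mm/pixel, both positive.
#' @return one-row data.frame: \code{areaCm2}, \code{pixelCountAreaCm2},
#'   \code{perimeterMm}, \code{diameterMm} (mean of the two converted axis
#'   lengths), \code{axisMajorMm}, \code{axisMinorMm}.
#' @export
toMetric <- function(contour, ellipse, spacing) {
  if (any(spacing <= 0)) stop("pixel spacing must be positive")
  sx <- spacing[1L]; sy <- spacing[2L]
  lengthScale <- mean(c(sx, sy))
  if (abs(sx - sy) / sx > 0.01)
    warning("anisotropic pixel spacing: lengths use the mean spacing")
  if (contour$empty)
    return(data.frame(areaCm2 = NA_real_, pixelCountAreaCm2 = NA_real_,
                      perimeterMm = NA_real_, diameterMm = NA_real_,
                      axisMajorMm = NA_real_, axisMinorMm = NA_real_))
  data.frame(
    areaCm2 = contour$areaPx * sx * sy / 100,
    pixelCountAreaCm2 = contour$pixelCount * sx * sy / 100,
    perimeterMm = contour$perimeterPx * lengthScale,
    diameterMm = if (is.null(ellipse)) NA_real_ else
      (ellipse$axisMajorPx + ellipse$axisMinorPx) / 2 * lengthScale,
    axisMajorMm = if (is.null(ellipse)) NA_real_ else
      ellipse$axisMajorPx * lengthScale,
    axisMinorMm = if (is.null(ellipse)) NA_real_ else
      ellipse$axisMinorPx * lengthScale)
}

#' Per-frame feature extraction for one cine study
#'
#' Runs mask -> contour -> bounding ellipse -> metric conversion for every
#' frame and attaches the two QC metrics: relative roundness (computed in
#' pixel space, before metric conversion) and the Immerkaer inter-pixel
#' noise estimate on the centred crop of the raw frame.
#'
#' @param study a \linkS4class{CineStudy}.
#' @param masks logical/integer array of per-frame masks (H x W x n). Use
#'   \code{groundTruth(study)$masks} for passthrough or supply baseline
#'   segmentations; default segments every frame with
#'   \code{\link{segmentFrameBaseline}}.
#' @param cropSize centred crop for the noise estimate (default 80).
#' @param ellipse fit the bounding ellipse per frame (default TRUE). Skip it
#'   when only areas are needed: the diameter columns are then NA and the
#'   slowest per-frame step is avoided.
#' @return data.frame with one row per frame: \code{frame}, the metric
#'   geometry columns of \code{\link{toMetric}}, \code{roundness},
#'   \code{noiseSigma}, \code{emptyMask}, \code{borderTouching}.
#' @export
extractStudyFeatures <- function(study, masks = NULL, cropSize = 80L,
                                 ellipse = TRUE) {
  stopifnot(is(study, "CineStudy"))
  n <- nFrames(study)
  img <- frames(study)
  if (is.null(masks)) {
    masks <- array(0L, dim = dim(img))
    for (f in seq_len(n)) masks[, , f] <- segmentFrameBaseline(img[, , f])
  }
  stopifnot(identical(dim(masks), dim(img)))
  rows <- vector("list", n)
  for (f in seq_len(n)) {
    ct <- extractContour(masks[, , f] * 1L)
    ell <- if (ct$empty || !ellipse) NULL else minBoundingEllipse(ct)
    met <- toMetric(ct, ell, pixelSpacing(study))
    met$frame <- f
    met$roundness <- if (ct$empty) NA_real_ else
      relativeRoundness(ct$areaPx, ct$perimeterPx)
    met$noiseSigma <- interpixelVariance(img[, , f], crop = cropSize)
    met$emptyMask <- ct$empty
    met$borderTouching <- ct$borderTouching
    rows[[f]] <- met
  }
  out <- do.call(rbind, rows)
  out[, c("frame", "areaCm2", "pixelCountAreaCm2", "perimeterMm",
          "diameterMm", "axisMajorMm", "axisMinorMm", "roundness",
          "noiseSigma", "emptyMask", "borderTouching")]
}

#' Write per-frame features keyed by (participant, frame)
#'
#' @param features data.frame from \code{\link{extractStudyFeatures}}.
#' @param participant participant id to key rows by.
#' @param path tab-delimited output path.
#' @export
writeFrameFeatures <- function(features, participant, path) {
  utils::write.table(cbind(participant = participant, features), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
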