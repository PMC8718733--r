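#' Baseline lumen segmentation of a single frame
#'
#' Classical stand-in segmenter: a global Otsu threshold splits the bright
#' lumen from the darker background, connected components are labelled, and
#' the component best matching the expected lumen position is kept via
#' \code{\link{selectPrimaryComponent}}. Components below a minimum pixel
#' floor (speckle) never qualify. A constant or featureless frame yields an
#' empty mask, not an error.
#'
#' @param image numeric matrix of brightness values (any monotone scale).
#' @param referencePoint (row, col) the lumen is expected near; defaults to
#'   the image centre, matching an acquisition protocol that centres the
#'   ascending aorta in the plane.
#' @param minSize minimum component size in pixels (default 20).
#' @return integer 0/1 matrix of the same shape.
#' @examples
#' img <- matrix(0, 64, 64); img[20:40, 20:40] <- 200
#' sum(segmentFrameBaseline(img))
#' @export
segmentFrameBaseline <- function(image, referencePoint = NULL, minSize = 20L) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps)
    return(matrix(0L, nrow(image), ncol(image)))
  scaled <- (image - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  mask <- (scaled > th) * 1L
  dim(mask) <- dim(image)
  selectPrimaryComponent(mask, referencePoint = referencePoint,
                         minSize = minSize)
}

#' Keep the single component most consistent with the expected lumen
#'
#' Labels the 8-connected components of a binary mask and keeps only the one
#' maximizing \code{size / (1 + distance of its centroid to the reference
#' point)}; everything else is zeroed. With equally sized components the
#' nearer one wins. An empty mask (or one with no component above
#' \code{minSize}) comes back empty.
#'
#' @param mask integer/logical matrix, values in \{0, 1\}.
#' @param referencePoint (row, col); default image centre.
#' @param minSize components smaller than this are ignored (default 0, i.e.
#'   no floor beyond non-emptiness).
#' @return integer 0/1 matrix.
#' @export
selectPrimaryComponent <- function(mask, referencePoint = NULL, minSize = 0L) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  if (!any(m == 1L)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (is.null(referencePoint))
    referencePoint <- (dim(m) + 1) / 2
  lab <- EBImage::bwlabel(m)
  labv <- as.integer(lab)
  sizes <- tabulate(labv)
  keepable <- which(sizes >= max(1L, as.integer(minSize)))
  if (!length(keepable)) return(matrix(0L, nrow(mask), ncol(mask)))
  score <- vapply(keepable, function(l) {
    idx <- which(labv == l)
    r <- ((idx - 1L) %% nrow(m)) + 1L
    cl <- ((idx - 1L) %/% nrow(m)) + 1L
    d <- sqrt((mean(r) - referencePoint[1L])^2 +
              (mean(cl) - referencePoint[2L])^2)
    sizes[l] / (1 + d)
  }, numeric(1))
  best <- keepable[which.max(score)]
  out <- (labv == best) * 1L
  dim(out) <- dim(m)
  out
}

#' Read an external segmentation source (directory of mask PNGs)
#'
#' Adapter for external models: accepts a directory of per-frame mask PNGs
#' named \code{frame_<index>.png} (1-based) and returns them as a logical
#' array ordered by frame index.
#'
#' @param path directory containing mask PNGs.
#' @return logical array (H x W x n).
#' @export
readMaskDirectory <- function(path) {
  files <- list.files(path, pattern = "^frame_\\d+\\.png$", full.names = TRUE)
  if (!length(files)) stop("no frame_<index>.png masks found in ", path)
  idx <- as.integer(sub("^frame_(\\d+)\\.png$", "\\1", basename(files)))
  files <- files[order(idx)]
  imgs <- lapply(files, function(f) png::readPNG(f))
  imgs <- lapply(imgs, function(im) {
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    im > 0.5
  })
  array(unlist(imgs), dim = c(dim(imgs[[1L]]), length(imgs)))
}
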