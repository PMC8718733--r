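#' Write a cine study as per-frame PNGs with a JSON sidecar
#'
#' Frames go to \code{frame_<i>.png} (brightness scaled 0--255 to 0--1),
#' ground-truth masks (when present) to \code{masks/frame_<i>.png}, and
#' \code{study.json} carries the pixel spacing (mm), frame order, id and
#' covariates.
#'
#' @param study a \linkS4class{CineStudy}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCineStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nFrames(study)
  for (f in seq_len(n))
    png::writePNG(frames(study)[, , f] / 255,
                  file.path(dir, sprintf("frame_%d.png", f)))
  gt <- groundTruth(study)
  if (!is.null(gt)) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (f in seq_len(n))
      png::writePNG(gt$masks[, , f] * 1,
                    file.path(dir, "masks", sprintf("frame_%d.png", f)))
  }
  meta <- list(participantId = participantId(study),
               pixelSpacingMm = pixelSpacing(study),
               frameOrder = sprintf("frame_%d.png", seq_len(n)),
               covariates = covariates(study))
  jsonlite::write_json(meta, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cine study written by \code{\link{writeCineStudy}}
#'
#' @param dir directory holding \code{frame_<i>.png} and \code{study.json}.
#' @return a \linkS4class{CineStudy} (ground truth not reattached; read
#'   masks with \code{\link{readMaskDirectory}} on \code{dir/masks}).
#' @export
readCineStudy <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  imgs <- lapply(file.path(dir, meta$frameOrder), function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    im * 255
  })
  fr <- array(unlist(imgs), dim = c(dim(imgs[[1L]]), length(imgs)))
  new("CineStudy", frames = fr,
      pixelSpacing = as.numeric(meta$pixelSpacingMm),
      participantId = as.character(meta$participantId),
      covariates = as.list(meta$covariates), groundTruth = NULL)
}
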