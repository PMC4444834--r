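# Coordinate frames: mosaic pixel space <-> physical stage space, and
# objective paracentricity correction.

#' Create a stage point
#'
#' @param x,y stage coordinates in micrometres (equal-length vectors).
#' @return a [StagePoint-class].
#' @examples
#' stagePoint(100, 200)
#' @export
stagePoint <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || !all(is.finite(x)) ||
      !all(is.finite(y)))
    .stopInvalid("stage coordinates must be finite numbers")
  new("StagePoint", x = as.numeric(x), y = as.numeric(y))
}

#' Create an objective profile
#'
#' @param name objective identifier (e.g. "10x-dry").
#' @param magnification nominal magnification, > 0.
#' @param fovWidth,fovHeight field of view at zoom 1, micrometres.
#' @param paracentricityDx,paracentricityDy optical-centre offset relative
#'   to the reference objective, micrometres (reference = c(0, 0)).
#' @return an [ObjectiveProfile-class].
#' @examples
#' objectiveProfile("20x", 20, 750, 750, paracentricityDx = 3.2)
#' @export
objectiveProfile <- function(name, magnification, fovWidth, fovHeight,
                             paracentricityDx = 0, paracentricityDy = 0) {
  new("ObjectiveProfile", name = name,
      magnification = as.numeric(magnification),
      fovWidth = as.numeric(fovWidth), fovHeight = as.numeric(fovHeight),
      paracentricityDx = as.numeric(paracentricityDx),
      paracentricityDy = as.numeric(paracentricityDy))
}

#' Create a mosaic frame
#'
#' @param origin [StagePoint-class]: stage position of the centre of
#'   pixel (0, 0).
#' @param pixelSize micrometres per pixel, > 0.
#' @param yAxisSign +1 if the pixel row index increases with stage Y,
#'   -1 otherwise.
#' @return a [MosaicFrame-class].
#' @examples
#' mosaicFrame(stagePoint(0, 0), pixelSize = 2)
#' @export
mosaicFrame <- function(origin, pixelSize, yAxisSign = 1) {
  new("MosaicFrame", origin = origin, pixelSize = as.numeric(pixelSize),
      yAxisSign = as.numeric(yAxisSign))
}

#' Map mosaic pixel coordinates to the stage
#'
#' Pixel indices are 0-based, refer to pixel centres and may be fractional
#' (sub-pixel centroids). `x = origin.x + col * pixelSize`;
#' `y = origin.y + yAxisSign * row * pixelSize`.
#'
#' @param frame a [MosaicFrame-class].
#' @param col,row continuous 0-based pixel coordinates (equal length).
#' @return a [StagePoint-class].
#' @seealso [stageToPixel()] for the exact inverse.
#' @examples
#' f <- mosaicFrame(stagePoint(0, 0), 2, yAxisSign = -1)
#' pixelToStage(f, 10, 10)   # (20, -20) um
#' @export
pixelToStage <- function(frame, col, row) {
  stopifnot(is(frame, "MosaicFrame"))
  if (!all(is.finite(col)) || !all(is.finite(row)))
    .stopInvalid("pixel coordinates must be finite")
  stagePoint(frame@origin@x + col * frame@pixelSize,
             frame@origin@y + frame@yAxisSign * row * frame@pixelSize)
}

#' Map a stage point to continuous mosaic pixel coordinates
#'
#' Exact inverse of [pixelToStage()].
#'
#' @param frame a [MosaicFrame-class].
#' @param point a [StagePoint-class] (possibly vectorized).
#' @return numeric matrix with columns `col`, `row` (0-based, continuous).
#' @examples
#' f <- mosaicFrame(stagePoint(50, 50), 5)
#' stageToPixel(f, stagePoint(55, 60))  # col 1, row 2
#' @export
stageToPixel <- function(frame, point) {
  stopifnot(is(frame, "MosaicFrame"), is(point, "StagePoint"))
  cbind(col = (point@x - frame@origin@x) / frame@pixelSize,
        row = frame@yAxisSign * (point@y - frame@origin@y) / frame@pixelSize)
}

#' Apply paracentricity correction for an objective change
#'
#' Coordinates measured under objective `from` are re-expressed as the
#' stage request that centres the same physical spot under objective
#' `to`: `point + (to.offset - from.offset)`. Corrections compose
#' additively (A->B then B->C equals A->C) and invert exactly.
#'
#' @param point a [StagePoint-class].
#' @param from,to [ObjectiveProfile-class]s sharing the same reference
#'   objective.
#' @return the corrected [StagePoint-class].
#' @examples
#' a <- objectiveProfile("10x", 10, 1500, 1500)
#' b <- objectiveProfile("40x", 40, 375, 375, 3, -2)
#' applyParacentricity(stagePoint(100, 100), a, b)  # (103, 98)
#' @export
applyParacentricity <- function(point, from, to) {
  stopifnot(is(point, "StagePoint"), is(from, "ObjectiveProfile"),
            is(to, "ObjectiveProfile"))
  stagePoint(point@x + (to@paracentricityDx - from@paracentricityDx),
             point@y + (to@paracentricityDy - from@paracentricityDy))
}

# --- frame serialization (JSON fragment shared by manifests and the
#     external-macro contract) ---

.frameToList <- function(frame, dim = NULL) {
  out <- list(origin_x_um = frame@origin@x, origin_y_um = frame@origin@y,
              pixel_size_um = frame@pixelSize, y_axis_sign = frame@yAxisSign)
  if (!is.null(dim)) {
    out$height_px <- as.numeric(dim[1])
    out$width_px <- as.numeric(dim[2])
  }
  out
}

.frameFromList <- function(x) {
  mosaicFrame(stagePoint(x$origin_x_um, x$origin_y_um), x$pixel_size_um,
              x$y_axis_sign)
}

#' Write / read a mosaic frame as JSON
#'
#' The frame file accompanies a stitched mosaic TIFF and is part of the
#' external-macro contract: it carries the pixel-to-stage mapping and the
#' mosaic dimensions.
#'
#' @param frame a [MosaicFrame-class].
#' @param dim optional `c(rows, cols)` of the mosaic image.
#' @param path file path.
#' @return `writeFrame` the path, invisibly; `readFrame` a list with
#'   elements `frame` ([MosaicFrame-class]) and `dim` (or NULL).
#' @export
writeFrame <- function(frame, path, dim = NULL) {
  .writeCanonicalJSON(c(list(schema_version = 1), .frameToList(frame, dim)),
                      path)
}

#' @rdname writeFrame
#' @export
readFrame <- function(path) {
  x <- .readJSON(path)
  d <- if (!is.null(x$height_px)) c(x$height_px, x$width_px) else NULL
  list(frame = .frameFromList(x), dim = d)
}

setMethod("show", "StagePoint", function(object) {
  n <- length(object@x)
  cat(sprintf("StagePoint(s): %d point(s)\n", n))
  k <- min(n, 3L)
  for (i in seq_len(k))
    cat(sprintf("  (%.3f, %.3f) um\n", object@x[i], object@y[i]))
  if (n > k) cat("  ...\n")
})

setMethod("show", "MosaicFrame", function(object) {
  cat(sprintf(
    "MosaicFrame: origin (%.3f, %.3f) um, %.4g um/px, y sign %+d\n",
    object@origin@x, object@origin@y, object@pixelSize,
    as.integer(object@yAxisSign)))
})

setMethod("show", "ObjectiveProfile", function(object) {
  cat(sprintf(
    "ObjectiveProfile '%s': %gx, FOV %g x %g um, paracentricity (%g, %g) um\n",
    object@name, object@magnification, object@fovWidth, object@fovHeight,
    object@paracentricityDx, object@paracentricityDy))
})
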