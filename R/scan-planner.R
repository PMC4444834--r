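# Second-scan planning: search mosaic layout, per-object plans (single
# field vs tile mosaic), NoIR pruning, object merging and the savings
# estimate.

#' Create a single second-scan field
#'
#' @param center [StagePoint-class] of the field centre.
#' @param width,height field size, micrometres.
#' @param id item identifier.
#' @return a [SingleField-class].
#' @export
singleField <- function(center, width, height, id = "field") {
  new("SingleField", id = id, center = center, width = as.numeric(width),
      height = as.numeric(height))
}

.gridAxisCenters <- function(lo, extent, fov, step) {
  # First tile centred at lo + fov/2; the last one shifted inward to
  # lo + extent - fov/2 so the grid never overhangs the bounds by more
  # than fov/2. A sample smaller than the field gets one centred tile.
  if (extent <= fov) return(lo + extent / 2)
  n <- ceiling((extent - fov) / step) + 1
  c(lo + fov / 2 + (seq_len(n - 1) - 1) * step, lo + extent - fov / 2)
}

#' Plan the first-scan search mosaic
#'
#' Lays out a grid of juxtaposed fields covering the whole sample bounds
#' at the given effective field of view and overlap. Column count is 1
#' when the sample is narrower than one field, otherwise
#' `ceil((w - fov_w) / step_w) + 1` with `step = fov * (1 - overlap)`
#' (rows analogous); every point of the bounds lies in at least one tile
#' and all tiles start enabled.
#'
#' @param bounds sample rectangle `c(x, y, w, h)` in micrometres
#'   (see [rectUm()]).
#' @param fov effective field of view `c(w, h)`, micrometres.
#' @param overlap overlap fraction in [0, 0.9].
#' @param id grid identifier.
#' @return a [TileGrid-class] with all tiles enabled.
#' @examples
#' g <- planSearchMosaic(rectUm(0, 0, 1000, 500), c(250, 250), 0)
#' dim(enabledMask(g))   # 2 rows x 4 cols
#' @export
planSearchMosaic <- function(bounds, fov, overlap = 0, id = "search") {
  bounds <- .asRect(bounds)
  if (length(fov) != 2L || any(fov <= 0))
    .stopInvalid("fov must be two positive lengths")
  if (!is.finite(overlap) || overlap < 0 || overlap >= 1)
    .stopInvalid("overlap must be in [0, 1); got %s", format(overlap))
  if (overlap > 0.9)
    .stopInvalid("overlap above 0.9 leaves no usable step")
  if (any(bounds[c("w", "h")] <= 0))
    .stopInvalid("bounds must have positive size")
  step <- fov * (1 - overlap)
  cx <- .gridAxisCenters(bounds[["x"]], bounds[["w"]], fov[[1]], step[[1]])
  cy <- .gridAxisCenters(bounds[["y"]], bounds[["h"]], fov[[2]], step[[2]])
  new("TileGrid", id = id, tileW = fov[[1]], tileH = fov[[2]],
      overlap = as.numeric(overlap), colCenters = cx, rowCenters = cy,
      enabled = matrix(TRUE, length(cy), length(cx)))
}

#' Tile positions in acquisition order
#'
#' Tiles are visited row-major in a serpentine (boustrophedon) path -
#' even rows left to right, odd rows right to left - which minimizes
#' stage travel and makes downstream stitching deterministic.
#'
#' @param grid a [TileGrid-class].
#' @param enabledOnly drop NoIR-disabled tiles (default TRUE).
#' @return data.frame: `tile_id`, `row`, `col` (0-based), `cx`, `cy`
#'   (centre, um), `x0`, `y0`, `x1`, `y1` (tile rectangle, um).
#' @export
tilePositions <- function(grid, enabledOnly = TRUE) {
  stopifnot(is(grid, "TileGrid"))
  nr <- length(grid@rowCenters); nc <- length(grid@colCenters)
  rows <- rep(seq_len(nr) - 1L, each = nc)
  cols <- unlist(lapply(seq_len(nr) - 1L, function(r)
    if (r %% 2L == 0L) seq_len(nc) - 1L else rev(seq_len(nc) - 1L)))
  keep <- if (enabledOnly)
    grid@enabled[cbind(rows + 1L, cols + 1L)] else rep(TRUE, length(rows))
  rows <- rows[keep]; cols <- cols[keep]
  cx <- grid@colCenters[cols + 1L]; cy <- grid@rowCenters[rows + 1L]
  data.frame(tile_id = sprintf("%s_r%d_c%d", grid@id, rows, cols),
             row = rows, col = cols, cx = cx, cy = cy,
             x0 = cx - grid@tileW / 2, y0 = cy - grid@tileH / 2,
             x1 = cx + grid@tileW / 2, y1 = cy + grid@tileH / 2)
}

#' Enabled-tile mask of a grid
#'
#' @param grid a [TileGrid-class].
#' @return logical rows x cols matrix.
#' @export
enabledMask <- function(grid) grid@enabled

#' Plan the acquisition of one detected object
#'
#' An object whose padded bounding box (box plus `margin` on every side)
#' fits within the second-scan field of view in both axes is captured as
#' one [SingleField-class] centred on its centroid; a bigger object is
#' covered by a [TileGrid-class] laid out over the padded box exactly as
#' [planSearchMosaic()] would. A padded box exactly equal to the field
#' resolves to the cheaper single field.
#'
#' @param obj a [DetectedObject-class].
#' @param fov2 second-scan effective field of view `c(w, h)`, micrometres.
#' @param overlap tile overlap fraction for grids.
#' @param margin context margin around the box, micrometres.
#' @return a [SingleField-class] or [TileGrid-class].
#' @export
planObjectAcquisition <- function(obj, fov2, overlap = 0, margin = 0) {
  stopifnot(is(obj, "DetectedObject"))
  if (length(fov2) != 2L || any(fov2 <= 0))
    .stopInvalid("fov2 must be two positive lengths")
  b <- obj@bboxUm
  padW <- b[["w"]] + 2 * margin
  padH <- b[["h"]] + 2 * margin
  if (padW <= fov2[[1]] && padH <= fov2[[2]])
    return(singleField(obj@centroid, fov2[[1]], fov2[[2]], id = obj@objectId))
  planSearchMosaic(rectUm(b[["x"]] - margin, b[["y"]] - margin, padW, padH),
                   fov2, overlap, id = obj@objectId)
}

#' Assemble the second-scan plan for a set of objects
#'
#' @param objects list of [DetectedObject-class].
#' @param settings the second-scan [AcquisitionSettings-class] (supplies
#'   the effective field of view and the settings id).
#' @param overlap tile overlap fraction for object mosaics.
#' @param margin context margin, micrometres.
#' @return a [SecondScanPlan-class].
#' @export
planSecondScan <- function(objects, settings, overlap = 0, margin = 0) {
  fov2 <- unname(effectiveFov(settings))
  entries <- lapply(objects, planObjectAcquisition, fov2 = fov2,
                    overlap = overlap, margin = margin)
  names(entries) <- vapply(objects, function(o) o@objectId, character(1))
  new("SecondScanPlan", entries = entries, settingsId = settings@id,
      fov = fov2, overlap = as.numeric(overlap))
}

# Integral image for O(1) any-pixel-in-window queries.
.integralImage <- function(m) {
  s <- apply(m, 2L, cumsum)
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(m))
  s <- t(apply(s, 1L, cumsum))
  if (is.null(dim(s))) s <- matrix(s, ncol = ncol(m))
  rbind(0, cbind(0, s))
}

.windowSum <- function(S, r0, r1, c0, c1) {
  S[r1 + 1L, c1 + 1L] - S[r0, c1 + 1L] - S[r1 + 1L, c0] + S[r0, c0]
}

# Disc structuring element: offsets with hypot <= r pixels.
.discKernel <- function(r) {
  k <- floor(r)
  d <- seq(-k, k)
  outer(d, d, function(i, j) (i * i + j * j) <= r * r + 1e-12) * 1
}

#' Disable non-informative tiles (NoIR)
#'
#' Re-examines one object's pixel mask and disables every tile of its
#' grid that does not intersect the mask dilated by `marginUm` - the
#' secondary analysis that prevents acquisition of non-informative
#' regions around large, irregular objects. Dilation is morphological
#' (Euclidean disc of radius `marginUm / pixelSize` in mask raster
#' space); a tile stays enabled iff its closed stage rectangle intersects
#' a dilated mask pixel square, grazing contact included, so no object
#' pixel is ever dropped from coverage. The enabled set is always a
#' subset of the input enabled set; an empty mask disables every tile
#' and signals a warning.
#'
#' @param grid a [TileGrid-class].
#' @param mask logical matrix (rows x cols) in mosaic pixel space.
#' @param frame the [MosaicFrame-class] the mask lives in.
#' @param marginUm dilation margin, micrometres (default 0).
#' @param maskOffset integer `c(col0, row0)`: 0-based mosaic pixel of
#'   `mask[1, 1]` (for masks cropped to an object's bounding box).
#' @return the grid with its `enabled` mask pruned.
#' @seealso [estimateSavings()] for the resulting efficiency gain.
#' @export
applyNoir <- function(grid, mask, frame, marginUm = 0,
                      maskOffset = c(0L, 0L)) {
  stopifnot(is(grid, "TileGrid"), is(frame, "MosaicFrame"),
            is.logical(mask) || all(mask %in% c(0, 1)))
  if (!isTRUE(marginUm >= 0)) .stopInvalid("marginUm must be >= 0")
  mask <- mask != 0
  if (!any(mask)) {
    warning("applyNoir: empty object mask; all tiles disabled")
    grid@enabled[] <- FALSE
    return(grid)
  }
  ps <- frame@pixelSize
  rpx <- marginUm / ps
  off <- as.integer(maskOffset)
  if (rpx > 0) {
    # dilation larger than any mask-to-grid distance enables every tile
    gx <- range(c(grid@colCenters - grid@tileW / 2,
                  grid@colCenters + grid@tileW / 2))
    gy <- range(c(grid@rowCenters - grid@tileH / 2,
                  grid@rowCenters + grid@tileH / 2))
    gc <- (gx - frame@origin@x) / ps
    gr <- frame@yAxisSign * (gy - frame@origin@y) / ps
    allC <- c(gc, off[1], off[1] + ncol(mask) - 1)
    allR <- c(gr, off[2], off[2] + nrow(mask) - 1)
    colSpan <- max(allC) - min(allC)
    rowSpan <- max(allR) - min(allR)
    if (rpx >= sqrt(colSpan^2 + rowSpan^2) + 1) return(grid)
  }
  pad <- ceiling(rpx)
  if (rpx > 0) {
    padded <- matrix(FALSE, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
    padded[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
    mask <- EBImage::dilate(EBImage::Image(padded * 1), .discKernel(rpx)) > 0
    mask <- matrix(as.logical(mask), nrow(padded), ncol(padded))
    off <- off - pad
  }
  S <- .integralImage(mask)
  eps <- 1e-9 * ps
  ox <- frame@origin@x; oy <- frame@origin@y; sgn <- frame@yAxisSign
  colRange <- function(x0, x1) {
    c(ceiling((x0 - ox) / ps - 0.5 - 1e-9) ,
      floor((x1 - ox) / ps + 0.5 + 1e-9))
  }
  rowRange <- function(y0, y1) {
    if (sgn > 0)
      c(ceiling((y0 - oy) / ps - 0.5 - 1e-9),
        floor((y1 - oy) / ps + 0.5 + 1e-9))
    else
      c(ceiling((oy - y1) / ps - 0.5 - 1e-9),
        floor((oy - y0) / ps + 0.5 + 1e-9))
  }
  en <- grid@enabled
  halfW <- grid@tileW / 2; halfH <- grid@tileH / 2
  for (ri in seq_along(grid@rowCenters)) {
    rr <- rowRange(grid@rowCenters[ri] - halfH, grid@rowCenters[ri] + halfH)
    r0 <- max(rr[1] - off[2], 0); r1 <- min(rr[2] - off[2], nrow(mask) - 1L)
    if (r0 > r1) { en[ri, ] <- FALSE; next }
    for (ci in seq_along(grid@colCenters)) {
      if (!en[ri, ci]) next
      cr <- colRange(grid@colCenters[ci] - halfW, grid@colCenters[ci] + halfW)
      c0 <- max(cr[1] - off[1], 0); c1 <- min(cr[2] - off[1], ncol(mask) - 1L)
      en[ri, ci] <- c0 <= c1 &&
        .windowSum(S, r0 + 1L, r1 + 1L, c0 + 1L, c1 + 1L) > 0
    }
  }
  grid@enabled <- en
  grid
}

.bboxGap <- function(a, b) {
  dx <- max(0, max(a[["x"]] - (b[["x"]] + b[["w"]]),
                   b[["x"]] - (a[["x"]] + a[["w"]])))
  dy <- max(0, max(a[["y"]] - (b[["y"]] + b[["h"]]),
                   b[["y"]] - (a[["y"]] + a[["h"]])))
  sqrt(dx * dx + dy * dy)
}

.mergeCluster <- function(objs) {
  if (length(objs) == 1L) return(objs[[1]])
  boxes <- lapply(objs, function(o) o@bboxUm)
  x0 <- min(vapply(boxes, `[[`, numeric(1), "x"))
  y0 <- min(vapply(boxes, `[[`, numeric(1), "y"))
  x1 <- max(vapply(boxes, function(b) b[["x"]] + b[["w"]], numeric(1)))
  y1 <- max(vapply(boxes, function(b) b[["y"]] + b[["h"]], numeric(1)))
  w <- vapply(objs, function(o)
    if (o@areaUm2 > 0) o@areaUm2 else prod(o@bboxUm[c("w", "h")]),
    numeric(1))
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  cx <- sum(w * vapply(objs, function(o) o@centroid@x, numeric(1)))
  cy <- sum(w * vapply(objs, function(o) o@centroid@y, numeric(1)))
  # union mask in mosaic pixel space (all objects share the mosaic frame)
  offs <- vapply(objs, function(o) o@maskOffset, integer(2))
  dims <- vapply(objs, function(o) dim(o@mask), integer(2))
  haveMasks <- all(dims[1, ] > 0)
  if (haveMasks) {
    c0 <- min(offs[1, ]); r0 <- min(offs[2, ])
    c1 <- max(offs[1, ] + dims[2, ] - 1L); r1 <- max(offs[2, ] + dims[1, ] - 1L)
    m <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    for (o in objs) {
      rr <- (o@maskOffset[2] - r0) + seq_len(nrow(o@mask))
      cc <- (o@maskOffset[1] - c0) + seq_len(ncol(o@mask))
      m[rr, cc] <- m[rr, cc] | o@mask
    }
    off <- c(c0, r0)
  } else {
    m <- matrix(logical(), 0, 0); off <- c(0L, 0L)
  }
  stats <- Reduce(`+`, lapply(seq_along(objs), function(i)
    w[i] * objs[[i]]@channelStats))
  if (is.null(stats)) stats <- numeric()
  largest <- which.max(vapply(objs, function(o) o@areaUm2, numeric(1)))
  ids <- sort(vapply(objs, function(o) o@objectId, character(1)))
  new("DetectedObject", objectId = paste(ids, collapse = "+"),
      label = objs[[largest]]@label, centroid = stagePoint(cx, cy),
      bboxUm = c(x = x0, y = y0, w = x1 - x0, h = y1 - y0),
      areaUm2 = sum(vapply(objs, function(o) o@areaUm2, numeric(1))),
      channelStats = stats,
      score = max(vapply(objs, function(o) o@score, numeric(1))),
      mask = m, maskOffset = as.integer(off),
      border = any(vapply(objs, function(o) o@border, logical(1))))
}

#' Merge objects closer than a separation threshold
#'
#' Objects whose bounding boxes lie within `minSeparation` of each other
#' (Euclidean gap between boxes; overlapping or abutting boxes have gap
#' 0) are merged into one object with the union bounding box, the union
#' mask, and an area-weighted centroid. Merging is transitive and is
#' repeated until a fixed point, so the result is idempotent: merged
#' boxes that come within the threshold of further objects are merged
#' again. Prevents overlapping second-scan plans.
#'
#' @param objects list of [DetectedObject-class] sharing one mosaic frame.
#' @param minSeparation micrometres, >= 0.
#' @return list of merged [DetectedObject-class].
#' @export
mergeNearbyObjects <- function(objects, minSeparation) {
  stopifnot(minSeparation >= 0)
  repeat {
    n <- length(objects)
    if (n <= 1L) return(objects)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (.bboxGap(objects[[i]]@bboxUm, objects[[j]]@bboxUm) <= minSeparation) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    if (length(unique(roots)) == n) return(objects)
    objects <- lapply(split(objects, roots), .mergeCluster)
    names(objects) <- NULL
  }
}

.planEnabledCount <- function(plan) {
  sum(vapply(plan@entries, function(e)
    if (is(e, "SingleField")) 1 else sum(e@enabled), numeric(1)))
}

#' Fraction of second-scan fields saved
#'
#' Compares the number of enabled fields in a plan with the field count
#' of a full mosaic over the baseline bounds at the same field of view
#' and overlap: `1 - enabled / full`, clamped to [0, 1]. This is the
#' capturing-efficiency gain of restricting the second scan to objects
#' of interest (and of NoIR pruning within them).
#'
#' @param plan a [SecondScanPlan-class].
#' @param baselineBounds rectangle `c(x, y, w, h)`, micrometres.
#' @return fraction in [0, 1].
#' @export
estimateSavings <- function(plan, baselineBounds) {
  stopifnot(is(plan, "SecondScanPlan"))
  full <- planSearchMosaic(baselineBounds, plan@fov, plan@overlap)
  total <- length(full@rowCenters) * length(full@colCenters)
  min(1, max(0, 1 - .planEnabledCount(plan) / total))
}

# Shift an item's geometry by (dx, dy) um - used for paracentricity
# correction when the second scan uses a different objective.
.shiftItem <- function(item, dx, dy) {
  if (is(item, "SingleField")) {
    item@center <- stagePoint(item@center@x + dx, item@center@y + dy)
  } else {
    item@colCenters <- item@colCenters + dx
    item@rowCenters <- item@rowCenters + dy
  }
  item
}

setMethod("show", "TileGrid", function(object) {
  cat(sprintf(
    "TileGrid '%s': %d x %d tiles of %g x %g um, overlap %g, %d/%d enabled\n",
    object@id, length(object@rowCenters), length(object@colCenters),
    object@tileW, object@tileH, object@overlap, sum(object@enabled),
    length(object@enabled)))
})

setMethod("show", "SingleField", function(object) {
  cat(sprintf("SingleField '%s': %g x %g um at (%.2f, %.2f)\n", object@id,
              object@width, object@height, object@center@x,
              object@center@y))
})

setMethod("show", "SecondScanPlan", function(object) {
  nf <- sum(vapply(object@entries, is, logical(1), "SingleField"))
  cat(sprintf(
    "SecondScanPlan [%s]: %d object(s) - %d single field(s), %d grid(s), %d enabled fields\n",
    object@settingsId, length(object@entries), nf,
    length(object@entries) - nf, .planEnabledCount(object)))
})
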