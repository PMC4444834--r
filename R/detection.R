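# Built-in image-analysis macros: tissue-piece detection and rare-event
# (CTC-style) multi-marker classification, plus the external-macro and
# manual-selection contracts.

#' Create detection parameters
#'
#' @param channel channel the pipeline segments.
#' @param thresholdMode "otsu" (default) or "fixed".
#' @param thresholdValue intensity cutoff for fixed mode.
#' @param smoothingSigma Gaussian sigma, pixels (0 disables smoothing).
#' @param minArea,maxArea component area window, square micrometres.
#' @return a [DetectionParams-class].
#' @export
detectionParams <- function(channel, thresholdMode = "otsu",
                            thresholdValue = NA_real_, smoothingSigma = 1,
                            minArea = 0, maxArea = Inf) {
  new("DetectionParams", channel = channel, thresholdMode = thresholdMode,
      thresholdValue = as.numeric(thresholdValue),
      smoothingSigma = as.numeric(smoothingSigma),
      minArea = as.numeric(minArea), maxArea = as.numeric(maxArea))
}

#' Create a marker rule
#'
#' @param channel marker channel.
#' @param polarity "positive" (mean >= threshold required) or "negative"
#'   (mean strictly below threshold required).
#' @param threshold mean-intensity cutoff.
#' @return a [MarkerRule-class].
#' @export
markerRule <- function(channel, polarity, threshold) {
  new("MarkerRule", channel = channel, polarity = polarity,
      threshold = as.numeric(threshold))
}

.getChannel <- function(image, name) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L)
  nm <- dimnames(image)[[3]]
  if (is.null(nm) || !name %in% nm)
    .stopInvalid("configuration error: channel '%s' not present (have: %s)",
                 name, paste(nm, collapse = ", "))
  image[, , name]
}

# Exact 8-connectivity labeling: 4-connected labels (EBImage::bwlabel)
# merged across diagonal contacts with union-find.
.label8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  n <- max(L)
  if (n < 2L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]    # down-right diagonal
  a2 <- L[-1, -nc];  b2 <- L[-nr, -1]   # up-right diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(L)
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                        pmax(pairs[, 1], pairs[, 2])))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- L
  out[L > 0L] <- remap[L[L > 0L]]
  out
}

# Shared segmentation pipeline: optional Gaussian smoothing -> global
# threshold (fixed or Otsu) -> fill holes -> morphological closing
# (radius 1 px) -> 8-connected components -> area filter (um^2).
# Returns the label matrix and a per-component stats table ordered by
# descending area.
.segment <- function(img, params, pixelSize) {
  stopifnot(is(params, "DetectionParams"))
  if (!all(is.finite(img))) .stopInvalid("image must be finite")
  if (params@smoothingSigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = params@smoothingSigma))
  thr <- if (identical(params@thresholdMode, "fixed")) params@thresholdValue
         else EBImage::otsu(EBImage::Image(pmin(pmax(img, 0), 1)))
  mask <- img > thr
  if (!any(mask))
    return(list(labels = matrix(0L, nrow(img), ncol(img)),
                stats = NULL, threshold = thr))
  m <- EBImage::fillHull(EBImage::Image(mask * 1))
  m <- EBImage::closing(m, EBImage::makeBrush(3, shape = "box"))
  labels <- .label8(matrix(as.logical(m), nrow(img), ncol(img)))
  n <- max(labels)
  if (n == 0L)
    return(list(labels = labels, stats = NULL, threshold = thr))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr          # 0-based pixel row
  cols <- (idx - 1L) %/% nr         # 0-based pixel col
  area <- tabulate(lab, n)
  cx <- rowsum(cols, lab)[, 1] / area
  cy <- rowsum(rows, lab)[, 1] / area
  sp <- split(seq_along(lab), lab)
  rmin <- vapply(sp, function(s) min(rows[s]), numeric(1))
  rmax <- vapply(sp, function(s) max(rows[s]), numeric(1))
  cmin <- vapply(sp, function(s) min(cols[s]), numeric(1))
  cmax <- vapply(sp, function(s) max(cols[s]), numeric(1))
  st <- data.frame(label = seq_len(n), area_px = area, cx = cx, cy = cy,
                   rmin = rmin, rmax = rmax, cmin = cmin, cmax = cmax)
  areaUm2 <- st$area_px * pixelSize^2
  keep <- areaUm2 >= params@minArea & areaUm2 <= params@maxArea
  st <- st[keep, , drop = FALSE]
  st <- st[order(-st$area_px), , drop = FALSE]
  list(labels = labels, stats = st, threshold = thr)
}

# Per-label mean intensity of each channel over the label mask dilated by
# `dilatePx` (greyscale dilation; non-overlapping objects keep their own
# rim). Returns labels x channels matrix.
.labelChannelMeans <- function(labels, image, channelNames, dilatePx = 0) {
  L <- labels
  if (dilatePx > 0) {
    L <- EBImage::dilate(EBImage::Image(labels), .discKernel(dilatePx))
    L <- matrix(as.integer(round(as.numeric(L))), nrow(labels), ncol(labels))
  }
  idx <- which(L > 0L)
  lab <- L[idx]
  n <- max(labels)
  cnt <- tabulate(lab, n)
  out <- matrix(NA_real_, n, length(channelNames),
                dimnames = list(NULL, channelNames))
  for (ch in channelNames) {
    v <- .getChannel(image, ch)[idx]
    out[, ch] <- rowsum(v, lab)[, 1] / cnt
  }
  out
}

.objectFromStats <- function(st, labels, frame, label, channelStats, score,
                             idPrefix = "obj") {
  ps <- frame@pixelSize
  centroid <- pixelToStage(frame, st$cx, st$cy)
  # stage-space bounding box of the pixel extent (pixel squares)
  xs <- frame@origin@x + c(st$cmin - 0.5, st$cmax + 0.5) * ps
  ys <- frame@origin@y + frame@yAxisSign * c(st$rmin - 0.5, st$rmax + 0.5) * ps
  m <- labels[(st$rmin:st$rmax) + 1L, (st$cmin:st$cmax) + 1L, drop = FALSE]
  new("DetectedObject",
      objectId = sprintf("%s%04d", idPrefix, st$label),
      label = label, centroid = centroid,
      bboxUm = c(x = min(xs), y = min(ys), w = abs(diff(xs)),
                 h = abs(diff(ys))),
      areaUm2 = st$area_px * ps^2,
      channelStats = channelStats, score = score,
      mask = m == st$label, maskOffset = as.integer(c(st$cmin, st$rmin)),
      border = st$rmin == 0 || st$cmin == 0 ||
        st$rmax == nrow(labels) - 1L || st$cmax == ncol(labels) - 1L)
}

#' Detect tissue pieces in a search mosaic
#'
#' Segments every region of tissue in a single-channel mosaic:
#' optional Gaussian smoothing, global threshold (fixed or Otsu), hole
#' filling, morphological closing (radius 1 px), 8-connected components,
#' and an area filter in square micrometres. Objects are returned sorted
#' by descending area with sub-pixel centroids converted to stage
#' micrometres; objects touching the mosaic border are kept and flagged.
#' An all-background image yields an empty list, not an error.
#'
#' @param image numeric matrix (rows x cols), or a 3-D array with
#'   channel names from which `params@channel` is taken.
#' @param frame the mosaic's [MosaicFrame-class].
#' @param params a [DetectionParams-class].
#' @return list of [DetectedObject-class], largest first.
#' @export
detectTissue <- function(image, frame, params) {
  stopifnot(is(frame, "MosaicFrame"))
  img <- .getChannel(image, params@channel)
  seg <- .segment(img, params, frame@pixelSize)
  if (is.null(seg$stats) || nrow(seg$stats) == 0L) return(list())
  chNames <- if (is.matrix(image)) params@channel else dimnames(image)[[3]]
  means <- .labelChannelMeans(seg$labels, image, chNames)
  lapply(seq_len(nrow(seg$stats)), function(i) {
    st <- seg$stats[i, ]
    .objectFromStats(st, seg$labels, frame, "tissue",
                     channelStats = means[st$label, ],
                     score = st$area_px * frame@pixelSize^2,
                     idPrefix = "tissue")
  })
}

#' Detect rare marker-defined events
#'
#' The CTC-style macro: nuclei are segmented on the nucleus channel with
#' the [detectTissue()] pipeline; each nucleus region, dilated by 2 px to
#' include the cytoplasmic rim, is measured on every marker channel; a
#' cell is an event iff every positive rule's mean is >= its threshold
#' and every negative rule's mean is strictly below its threshold (e.g.
#' nucleated, cytokeratin-positive, CD45-negative). Only events are
#' returned; the score is the smallest rule margin.
#'
#' @param image 3-D array (rows x cols x channels) with channel dimnames.
#' @param frame the mosaic's [MosaicFrame-class].
#' @param nucleus [DetectionParams-class] for the nucleus channel.
#' @param rules list of [MarkerRule-class].
#' @return list of [DetectedObject-class] (label "event").
#' @export
detectRareEvents <- function(image, frame, nucleus, rules) {
  stopifnot(is(frame, "MosaicFrame"), length(dim(image)) == 3L)
  .getChannel(image, nucleus@channel)   # errors early if missing
  for (r in rules) .getChannel(image, r@channel)
  seg <- .segment(.getChannel(image, nucleus@channel), nucleus,
                  frame@pixelSize)
  if (is.null(seg$stats) || nrow(seg$stats) == 0L) return(list())
  chNames <- dimnames(image)[[3]]
  means <- .labelChannelMeans(seg$labels, image, chNames, dilatePx = 2)
  isEvent <- rep(TRUE, nrow(seg$stats))
  margin <- rep(Inf, nrow(seg$stats))
  for (r in rules) {
    m <- means[seg$stats$label, r@channel]
    if (identical(r@polarity, "positive")) {
      isEvent <- isEvent & m >= r@threshold
      margin <- pmin(margin, m - r@threshold)
    } else {
      isEvent <- isEvent & m < r@threshold
      margin <- pmin(margin, r@threshold - m)
    }
  }
  keep <- which(isEvent)
  lapply(keep, function(i) {
    st <- seg$stats[i, ]
    .objectFromStats(st, seg$labels, frame, "event",
                     channelStats = means[st$label, ],
                     score = margin[i], idPrefix = "event")
  })
}

#' Export detected objects as coordinate records
#'
#' @param objects list of [DetectedObject-class].
#' @return data.frame in the coordinate CSV contract (centroid + bounding
#'   box size + label + score).
#' @export
objectsToRecords <- function(objects) {
  if (length(objects) == 0L) return(emptyCoordinates())
  do.call(rbind, lapply(objects, function(o)
    data.frame(object_id = o@objectId, x_um = o@centroid@x,
               y_um = o@centroid@y, bbox_w_um = o@bboxUm[["w"]],
               bbox_h_um = o@bboxUm[["h"]], label = o@label,
               score = o@score)))
}

.mosaicExtent <- function(frame, dim) {
  ps <- frame@pixelSize
  xs <- frame@origin@x + c(-0.5, dim[2] - 0.5) * ps
  ys <- frame@origin@y + frame@yAxisSign * c(-0.5, dim[1] - 0.5) * ps
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

#' Run an external image-analysis macro
#'
#' The macro contract: any external routine participates as long as it
#' accepts the stitched mosaic TIFF path, the frame JSON path and an
#' output CSV path as its last three arguments and writes a coordinate
#' list in the CSV contract. A nonzero exit status or a missing/invalid
#' CSV raises a macro-contract error. Records whose centroids fall
#' outside the mosaic extent are rejected; the returned table carries
#' them in `attr(, "rejected")` and a report message lists their ids.
#'
#' @param command executable to run.
#' @param args extra arguments placed before the contract arguments.
#' @param mosaicPath path of the stitched mosaic TIFF.
#' @param framePath path of the frame JSON (see [writeFrame()]; must
#'   include the mosaic dimensions).
#' @param outputCsv path the macro must write.
#' @return accepted coordinate records (data.frame), with rejected rows
#'   in `attr(, "rejected")`.
#' @export
runExternalMacro <- function(command, args = character(), mosaicPath,
                             framePath, outputCsv = tempfile(fileext = ".csv")) {
  status <- system2(command, c(args, shQuote(mosaicPath), shQuote(framePath),
                               shQuote(outputCsv)))
  if (!identical(status, 0L))
    .stopInvalid("macro-contract error: '%s' exited with status %d",
                 command, status)
  if (!file.exists(outputCsv))
    .stopInvalid("macro-contract error: output CSV '%s' was not written",
                 outputCsv)
  records <- tryCatch(readCoordinates(outputCsv), error = function(e)
    .stopInvalid("macro-contract error: %s", conditionMessage(e)))
  fi <- readFrame(framePath)
  if (is.null(fi$dim))
    .stopInvalid("macro-contract error: frame JSON lacks mosaic dimensions")
  ext <- .mosaicExtent(fi$frame, fi$dim)
  ok <- records$x_um >= ext[["xmin"]] & records$x_um <= ext[["xmax"]] &
        records$y_um >= ext[["ymin"]] & records$y_um <= ext[["ymax"]]
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected) > 0L)
    message("runExternalMacro: rejected ", nrow(rejected),
            " out-of-bounds record(s): ",
            paste(rejected$object_id, collapse = ", "))
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Import a manual object selection
#'
#' Turns user-supplied coordinate records (objects picked on the search
#' mosaic) into detected objects with rectangular masks, label "manual".
#'
#' @param records coordinate records (see [readCoordinates()]).
#' @param frame the mosaic's [MosaicFrame-class].
#' @return list of [DetectedObject-class].
#' @export
importManualSelection <- function(records, frame) {
  records <- .checkCoordinates(records)
  lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ps <- frame@pixelSize
    px <- stageToPixel(frame, stagePoint(r$x_um, r$y_um))
    halfC <- r$bbox_w_um / 2 / ps
    halfR <- r$bbox_h_um / 2 / ps
    c0 <- floor(px[1, "col"] - halfC + 0.5); c1 <- ceiling(px[1, "col"] + halfC - 0.5)
    r0 <- floor(px[1, "row"] - halfR + 0.5); r1 <- ceiling(px[1, "row"] + halfR - 0.5)
    new("DetectedObject", objectId = r$object_id, label = "manual",
        centroid = stagePoint(r$x_um, r$y_um),
        bboxUm = c(x = r$x_um - r$bbox_w_um / 2, y = r$y_um - r$bbox_h_um / 2,
                   w = r$bbox_w_um, h = r$bbox_h_um),
        areaUm2 = r$bbox_w_um * r$bbox_h_um,
        channelStats = numeric(), score = r$score,
        mask = matrix(TRUE, r1 - r0 + 1L, c1 - c0 + 1L),
        maskOffset = as.integer(c(c0, r0)), border = FALSE)
  })
}

setMethod("show", "DetectedObject", function(object) {
  cat(sprintf(
    "DetectedObject '%s' [%s]: centroid (%.2f, %.2f) um, bbox %g x %g um, area %.1f um^2%s\n",
    object@objectId, object@label, object@centroid@x, object@centroid@y,
    object@bboxUm[["w"]], object@bboxUm[["h"]], object@areaUm2,
    if (object@border) " (border)" else ""))
})
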