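# Shared fixtures and independent oracles, all generated in code.

# --- random document generators -------------------------------------------

randomObjective <- function() {
  objectiveProfile(sample(c("5x", "10x", "20x", "40x", "63x"), 1),
                   magnification = sample(c(5, 10, 20, 40, 63), 1),
                   fovWidth = round(runif(1, 200, 3000), 3),
                   fovHeight = round(runif(1, 200, 3000), 3),
                   paracentricityDx = round(runif(1, -10, 10), 3),
                   paracentricityDy = round(runif(1, -10, 10), 3))
}

randomSettings <- function(id = "s") {
  nch <- sample(1:4, 1)
  acquisitionSettings(
    id = paste0(id, sample(1000:9999, 1)),
    objective = randomObjective(),
    zoom = round(runif(1, 1, 6), 3),
    imageWidth = sample(64:2048, 1), imageHeight = sample(64:2048, 1),
    channels = data.frame(name = paste0("ch", seq_len(nch)),
                          exposure = round(runif(nch, 0.01, 10), 3)),
    zStack = c(n_slices = sample(1:15, 1), step_um = round(runif(1, 0, 5), 3)),
    timeLapse = c(n_frames = sample(1:10, 1),
                  interval_s = round(runif(1, 0, 60), 3)))
}

randomCoordinates <- function(n = sample(0:20, 1)) {
  if (n == 0) return(emptyCoordinates())
  data.frame(object_id = sprintf("obj%03d", seq_len(n)),
             x_um = round(runif(n, -5000, 5000), 3),
             y_um = round(runif(n, -5000, 5000), 3),
             bbox_w_um = round(runif(n, 0, 800), 3),
             bbox_h_um = round(runif(n, 0, 800), 3),
             label = sample(c("tissue", "event", "manual"), n, TRUE),
             score = round(runif(n, 0, 1), 3))
}

randomTemplate <- function() {
  nRules <- sample(0:3, 1)
  screenTemplate(
    randomSettings("first"), randomSettings("second"),
    detectionParams(channel = "ch1",
                    thresholdMode = sample(c("otsu", "fixed"), 1),
                    thresholdValue = round(runif(1, 0, 1), 3),
                    smoothingSigma = round(runif(1, 0, 3), 3),
                    minArea = round(runif(1, 0, 100), 3),
                    maxArea = if (runif(1) < 0.5) Inf
                              else round(runif(1, 1000, 9000), 3)),
    macro = sample(c("tissue", "rare_events", "manual"), 1),
    markerRules = replicate(nRules, markerRule(
      paste0("ch", sample(1:4, 1)),
      sample(c("positive", "negative"), 1),
      round(runif(1, 0, 1), 3)), simplify = FALSE),
    noirEnabled = runif(1) < 0.5,
    noirMarginUm = round(runif(1, 0, 50), 3),
    planMarginUm = round(runif(1, 0, 50), 3),
    firstOverlap = round(runif(1, 0, 0.5), 3),
    secondOverlap = round(runif(1, 0, 0.5), 3),
    minSeparationUm = round(runif(1, 0, 100), 3),
    layout = slideLayout(sample(1:5, 1)))
}

# Minimal detected object with a rectangular mask in a 1 um/px frame.
makeObj <- function(id, x, y, w, h, area = w * h) {
  new("DetectedObject", objectId = id, label = "test",
      centroid = stagePoint(x + w / 2, y + h / 2),
      bboxUm = c(x = x, y = y, w = w, h = h), areaUm2 = area,
      channelStats = c(ch1 = 1), score = 1,
      mask = matrix(TRUE, max(1, round(h)), max(1, round(w))),
      maskOffset = as.integer(c(round(x), round(y))), border = FALSE)
}

# --- NoIR brute-force rasterization oracle --------------------------------

# Random NoIR problem: a tile grid (<= 16 x 16), a blobby mask rasterized
# at 1 um (pixel centres at half-integers), and a dilation margin.
randomNoirCase <- function(maxTiles = 16, maxMargin = 5) {
  nrT <- sample(1:maxTiles, 1); ncT <- sample(1:maxTiles, 1)
  t <- sample(6:9, 1)
  overlap <- sample(c(0, 0.1), 1)
  W <- ncT * t; H <- nrT * t
  grid <- planSearchMosaic(rectUm(0, 0, W, H), c(t, t), overlap)
  mask <- matrix(FALSE, H, W)
  for (k in seq_len(sample(1:4, 1))) {
    cx <- runif(1, 0, W); cy <- runif(1, 0, H); r <- runif(1, 2, W / 2)
    px <- outer(seq_len(H) - 0.5, seq_len(W) - 0.5, function(y, x)
      (x - cx)^2 + (y - cy)^2 <= r^2)
    mask <- mask | px
  }
  frame <- mosaicFrame(stagePoint(0.5, 0.5), 1, 1)
  list(grid = grid, mask = mask, frame = frame,
       margin = if (runif(1) < 0.3) 0 else runif(1, 0, maxMargin))
}

# Oracle: dilate the mask on its own 1 um lattice by shift-and-OR over
# the integer-offset Euclidean disc, then test every tile rectangle for
# overlap with a dilated pixel square (closed rectangles, grazing
# counts). Independent of the integral-image / greyscale-dilation path
# used by applyNoir().
noirOracle <- function(grid, mask, frame, margin) {
  ps <- frame@pixelSize
  stopifnot(ps == 1, frame@yAxisSign == 1)
  r <- margin / ps
  k <- floor(r)
  pad <- as.integer(k)
  H <- nrow(mask); W <- ncol(mask)
  dil <- matrix(FALSE, H + 2 * pad, W + 2 * pad)
  for (di in -k:k) for (dj in -k:k) {
    if (di * di + dj * dj <= r * r) {
      dil[pad + di + seq_len(H), pad + dj + seq_len(W)] <-
        dil[pad + di + seq_len(H), pad + dj + seq_len(W)] | mask
    }
  }
  # stage coords of dilated pixel centres
  idx <- which(dil)
  pr <- (idx - 1) %% nrow(dil) - pad          # 0-based mosaic pixel row
  pc <- (idx - 1) %/% nrow(dil) - pad
  pxx <- frame@origin@x + pc * ps
  pxy <- frame@origin@y + pr * ps
  tp <- tilePositions(grid, enabledOnly = FALSE)
  en <- matrix(FALSE, length(grid@rowCenters), length(grid@colCenters))
  for (i in seq_len(nrow(tp))) {
    hit <- any(pxx >= tp$x0[i] - ps / 2 & pxx <= tp$x1[i] + ps / 2 &
               pxy >= tp$y0[i] - ps / 2 & pxy <= tp$y1[i] + ps / 2)
    en[tp$row[i] + 1, tp$col[i] + 1] <- hit
  }
  en
}

# --- grid coverage oracle (axis-separable, 1 um pitch) --------------------

coverageFraction <- function(grid, bounds, pitch = 1) {
  covered1d <- function(samples, centers, half) {
    vapply(samples, function(p)
      any(abs(p - centers) <= half + 1e-9), logical(1))
  }
  xs <- seq(bounds[["x"]], bounds[["x"]] + bounds[["w"]], by = pitch)
  ys <- seq(bounds[["y"]], bounds[["y"]] + bounds[["h"]], by = pitch)
  cx <- covered1d(xs, grid@colCenters, grid@tileW / 2)
  cy <- covered1d(ys, grid@rowCenters, grid@tileH / 2)
  (sum(cx) * sum(cy)) / (length(xs) * length(ys))
}

# --- merge oracle: iterated transitive closure over the bbox-gap graph ---

rectGap <- function(a, b) {
  dx <- max(0, max(a[["x"]] - (b[["x"]] + b[["w"]]),
                   b[["x"]] - (a[["x"]] + a[["w"]])))
  dy <- max(0, max(a[["y"]] - (b[["y"]] + b[["h"]]),
                   b[["y"]] - (a[["y"]] + a[["h"]])))
  sqrt(dx^2 + dy^2)
}

mergeOracleBoxes <- function(boxes, minSep) {
  repeat {
    n <- length(boxes)
    if (n <= 1) return(boxes)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- rectGap(boxes[[i]], boxes[[j]]) <= minSep
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    if (max(comp) == n) return(boxes)
    boxes <- lapply(split(seq_len(n), comp), function(ix) {
      bs <- boxes[ix]
      x0 <- min(vapply(bs, `[[`, numeric(1), "x"))
      y0 <- min(vapply(bs, `[[`, numeric(1), "y"))
      x1 <- max(vapply(bs, function(b) b[["x"]] + b[["w"]], numeric(1)))
      y1 <- max(vapply(bs, function(b) b[["y"]] + b[["h"]], numeric(1)))
      c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
    })
    names(boxes) <- NULL
  }
}

sortedBoxKey <- function(boxes) {
  m <- do.call(rbind, lapply(boxes, function(b) round(unname(b), 6)))
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

# Match detected events to ground-truth events within a tolerance;
# returns c(truePos, falsePos, falseNeg).
scoreDetections <- function(objects, gtEvents, tolUm = 6) {
  used <- rep(FALSE, nrow(gtEvents))
  tp <- 0; fp <- 0
  for (o in objects) {
    d <- sqrt((gtEvents$x - o@centroid@x)^2 + (gtEvents$y - o@centroid@y)^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tolUm) {
      used[j] <- TRUE; tp <- tp + 1
    } else fp <- fp + 1
  }
  c(tp = tp, fp = fp, fn = sum(!used))
}

# Coverage of an object's mask by the enabled fields of its plan entry
# (all in the mask's own frame; pixel centres must lie in some enabled
# field rectangle).
maskCoveredByEntry <- function(obj, entry, frame) {
  idx <- which(obj@mask)
  if (!length(idx)) return(TRUE)
  pr <- (idx - 1) %% nrow(obj@mask) + obj@maskOffset[2]
  pc <- (idx - 1) %/% nrow(obj@mask) + obj@maskOffset[1]
  px <- frame@origin@x + pc * frame@pixelSize
  py <- frame@origin@y + frame@yAxisSign * pr * frame@pixelSize
  if (is(entry, "SingleField")) {
    return(all(px >= entry@center@x - entry@width / 2 - 1e-9 &
               px <= entry@center@x + entry@width / 2 + 1e-9 &
               py >= entry@center@y - entry@height / 2 - 1e-9 &
               py <= entry@center@y + entry@height / 2 + 1e-9))
  }
  tp <- tilePositions(entry)
  covered <- rep(FALSE, length(px))
  for (i in seq_len(nrow(tp)))
    covered <- covered | (px >= tp$x0[i] - 1e-9 & px <= tp$x1[i] + 1e-9 &
                          py >= tp$y0[i] - 1e-9 & py <= tp$y1[i] + 1e-9)
  all(covered)
}
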