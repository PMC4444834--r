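# Virtual microscope: synthetic-slide generator and renderer standing in
# for the physical instrument. The scene is an analytic intensity
# function (smooth compact object profiles over a uniform background),
# not a stored raster, so any field can be rendered at any pixel size
# consistently - the second scan genuinely sees more detail than the
# first. Gaussian read noise only; each acquisition item gets its own
# noise stream derived from (slide seed, item id) so re-acquisition is
# reproducible.

#' Tissue-microarray scene specification
#'
#' Differently sized smooth tissue pieces (rotated ellipses and low-order
#' Fourier blobs) on a dark background, emulating a TMA slide scanned
#' piece by piece. Defaults describe the reference scenario: 77 pieces
#' of 200-600 um diameter on a 10 x 10 mm scan area.
#'
#' @param nPieces number of tissue pieces.
#' @param extent scan area `c(w, h)`, micrometres.
#' @param pieceDiameter diameter range `c(min, max)`, micrometres.
#' @param intensity tissue intensity range (arbitrary units, [0, 1]).
#' @param shapes shape families to draw from ("ellipse", "blob").
#' @param background background intensity.
#' @param noiseSd Gaussian read-noise sd.
#' @param edgeUm width of the smooth intensity ramp at piece borders.
#' @param minSeparationUm minimum gap between pieces.
#' @param seed integer seed; the scene is fully determined by it.
#' @return a [SyntheticSampleSpec-class].
#' @export
tmaSpec <- function(nPieces = 77, extent = c(10000, 10000),
                    pieceDiameter = c(200, 600), intensity = c(0.5, 0.9),
                    shapes = c("ellipse", "blob"), background = 0.05,
                    noiseSd = 0.01, edgeUm = 8, minSeparationUm = 150,
                    seed = 1) {
  new("SyntheticSampleSpec", kind = "tma", extent = as.numeric(extent),
      channels = "tissue", background = as.numeric(background),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
      params = list(nPieces = nPieces, pieceDiameter = pieceDiameter,
                    intensity = intensity, shapes = shapes, edgeUm = edgeUm,
                    minSeparationUm = minSeparationUm))
}

#' Rare-event (CTC-style) cell-field specification
#'
#' A field of nucleated cells of which a small fraction are events:
#' cytokeratin-positive, CD45-negative cells among a CD45-positive
#' background population. Defaults mirror the reference assay: 10,000
#' cells with event fraction 0.0025 (1 in 400), and a signal-to-noise
#' ratio of (signal - background) / noiseSd = 5.
#'
#' @param nCells total cell count.
#' @param eventFraction fraction of events in [0, 1]; the slide carries
#'   exactly `round(nCells * eventFraction)` events.
#' @param extent scan area `c(w, h)`, micrometres.
#' @param nucleusRadiusUm,cytoRadiusUm nucleus and cytoplasm radii.
#' @param nucleusIntensity DAPI-channel intensity of every nucleus.
#' @param markerHigh,markerLow mean marker intensity of the
#'   expressing / non-expressing class (events: CK high, CD45 low;
#'   other cells: CK low, CD45 high).
#' @param markerSd per-cell marker intensity sd.
#' @param background background intensity on every channel.
#' @param noiseSd Gaussian read-noise sd.
#' @param edgeUm intensity ramp width at cell borders.
#' @param minSeparationUm minimum gap between cell cytoplasms.
#' @param seed integer seed.
#' @return a [SyntheticSampleSpec-class].
#' @export
ctcSpec <- function(nCells = 10000, eventFraction = 0.0025,
                    extent = c(3000, 3000), nucleusRadiusUm = 5,
                    cytoRadiusUm = 8, nucleusIntensity = 0.6,
                    markerHigh = 0.6, markerLow = 0.1, markerSd = 0.03,
                    background = 0.05, noiseSd = 0.11, edgeUm = 1.5,
                    minSeparationUm = 6, seed = 1) {
  new("SyntheticSampleSpec", kind = "ctc", extent = as.numeric(extent),
      channels = c("dapi", "ck", "cd45"),
      background = as.numeric(background), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed),
      params = list(nCells = nCells, eventFraction = eventFraction,
                    nucleusRadiusUm = nucleusRadiusUm,
                    cytoRadiusUm = cytoRadiusUm,
                    nucleusIntensity = nucleusIntensity,
                    markerHigh = markerHigh, markerLow = markerLow,
                    markerSd = markerSd, edgeUm = edgeUm,
                    minSeparationUm = minSeparationUm))
}

# Sequential non-overlap placement: rejection sampling (<= 1000 attempts
# per object) with a spatial hash for neighbour queries.
.placeObjects <- function(extent, radii, minSep, edge) {
  n <- length(radii)
  if (n == 0L) return(cbind(x = numeric(), y = numeric()))
  g <- 2 * max(radii) + minSep
  nx <- max(1L, ceiling(extent[1] / g)); ny <- max(1L, ceiling(extent[2] / g))
  bins <- vector("list", nx * ny)
  binOf <- function(x, y) {
    bx <- pmin(nx - 1L, pmax(0L, floor(x / g)))
    by <- pmin(ny - 1L, pmax(0L, floor(y / g)))
    bx * ny + by + 1L
  }
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    lo <- radii[i] + edge
    if (extent[1] <= 2 * lo || extent[2] <= 2 * lo)
      .stopInvalid("placement error: extent too small for object of radius %g",
                   radii[i])
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      x <- runif(1, lo, extent[1] - lo)
      y <- runif(1, lo, extent[2] - lo)
      bx <- floor(x / g); by <- floor(y / g)
      nb <- unlist(lapply(max(0, bx - 1):min(nx - 1, bx + 1), function(a)
        lapply(max(0, by - 1):min(ny - 1, by + 1), function(b)
          bins[[a * ny + b + 1L]])))
      ok <- TRUE
      if (length(nb)) {
        d <- sqrt((xs[nb] - x)^2 + (ys[nb] - y)^2)
        ok <- all(d >= radii[nb] + radii[i] + minSep)
      }
      if (ok) {
        xs[i] <- x; ys[i] <- y
        k <- binOf(x, y)
        bins[[k]] <- c(bins[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .stopInvalid("placement error: could not place object %d within 1000 attempts",
                   i)
  }
  cbind(x = xs, y = ys)
}

#' Generate a virtual slide
#'
#' Draws the ground-truth scene described by a
#' [SyntheticSampleSpec-class]: object shapes, intensities and
#' non-overlapping positions (rejection sampling, at most 1000 attempts
#' per object; failure raises a placement error). Deterministic for a
#' fixed seed. The caller's RNG state is untouched.
#'
#' @param spec a [SyntheticSampleSpec-class].
#' @return a [VirtualSlide-class] with a `groundTruth` table carrying
#'   per-object class labels, positions and intensities.
#' @examples
#' slide <- generateSlide(ctcSpec(nCells = 200, extent = c(600, 600),
#'                                seed = 7))
#' table(groundTruth(slide)$class)
#' @export
generateSlide <- function(spec) {
  stopifnot(is(spec, "SyntheticSampleSpec"))
  validObject(spec)
  .withSeed(spec@seed, {
    p <- spec@params
    if (spec@kind == "tma") {
      n <- p$nPieces
      shape <- sample(p$shapes, n, replace = TRUE)
      a <- runif(n, p$pieceDiameter[1] / 2, p$pieceDiameter[2] / 2)
      b <- a * runif(n, 0.6, 1)
      theta <- runif(n, 0, pi)
      amp <- runif(n, p$intensity[1], p$intensity[2])
      four <- lapply(seq_len(n), function(i) {
        if (shape[i] == "blob")
          list(k = 2:4, ak = runif(3, 0, 0.08), ph = runif(3, 0, 2 * pi))
        else NULL
      })
      rEff <- vapply(seq_len(n), function(i) {
        if (shape[i] == "blob") a[i] * (1 + sum(four[[i]]$ak)) else a[i]
      }, numeric(1))
      pos <- .placeObjects(spec@extent, rEff, p$minSeparationUm, p$edgeUm)
      objs <- lapply(seq_len(n), function(i) {
        list(kind = shape[i], x = pos[i, 1], y = pos[i, 2], a = a[i],
             b = b[i], theta = theta[i], four = four[[i]], rEff = rEff[i],
             amp = c(tissue = amp[i]), edge = p$edgeUm)
      })
      gt <- data.frame(id = sprintf("gt%04d", seq_len(n)),
                       class = rep("tissue", n),
                       x = pos[, 1], y = pos[, 2], radius = rEff,
                       intensity = amp)
    } else {
      n <- p$nCells
      nEvents <- round(n * p$eventFraction)
      cls <- c(rep("event", nEvents), rep("other", n - nEvents))
      rn <- p$nucleusRadiusUm * runif(n, 0.9, 1.1)
      rc <- pmax(rn + 1, p$cytoRadiusUm * runif(n, 0.9, 1.1))
      ck <- pmax(0, rnorm(n, ifelse(cls == "event", p$markerHigh,
                                    p$markerLow), p$markerSd))
      cd45 <- pmax(0, rnorm(n, ifelse(cls == "event", p$markerLow,
                                      p$markerHigh), p$markerSd))
      pos <- .placeObjects(spec@extent, rc, p$minSeparationUm, p$edgeUm)
      # shuffle so events are not clustered in placement order
      ord <- sample.int(n)
      cls <- cls[ord]; rn <- rn[ord]; rc <- rc[ord]
      ck <- ck[ord]; cd45 <- cd45[ord]
      objs <- lapply(seq_len(n), function(i) {
        list(kind = "cell", x = pos[i, 1], y = pos[i, 2], rn = rn[i],
             rc = rc[i], rEff = rc[i],
             amp = c(dapi = p$nucleusIntensity, ck = ck[i], cd45 = cd45[i]),
             edge = p$edgeUm)
      })
      gt <- data.frame(id = sprintf("gt%05d", seq_len(n)), class = cls,
                       x = pos[, 1], y = pos[, 2], radius = rc,
                       nucleus_radius = rn, ck = ck, cd45 = cd45)
    }
    new("VirtualSlide", spec = spec, groundTruth = gt, objects = objs)
  })
}

#' Ground truth and channels of a virtual slide
#'
#' @param slide a [VirtualSlide-class].
#' @return `groundTruth`: the per-object truth table; `slideChannels`:
#'   channel names the slide renders.
#' @export
groundTruth <- function(slide) slide@groundTruth

#' @rdname groundTruth
#' @export
slideChannels <- function(slide) slide@spec@channels

# Compactly supported smooth edge profile: 1 well inside, 0 beyond the
# ramp, cosine-smooth in between. d = signed distance to the boundary
# (negative inside), e = half ramp width.
.edgeProfile <- function(d, e) {
  ifelse(d <= -e, 1, ifelse(d >= e, 0, 0.5 * (1 - sin(pi * d / (2 * e)))))
}

# Contribution of one object to channel `ch` at pixel centres (X columns,
# Y rows); returns an outer-product style matrix [length(Y), length(X)].
.objectField <- function(o, ch, X, Y) {
  amp <- o$amp[[ch]]
  if (is.null(amp) || amp == 0) return(0)
  dx <- matrix(X - o$x, length(Y), length(X), byrow = TRUE)
  dy <- matrix(Y - o$y, length(Y), length(X))
  if (o$kind == "cell") {
    r <- sqrt(dx^2 + dy^2)
    R <- if (ch == "dapi") o$rn else o$rc
    return(amp * .edgeProfile(r - R, o$edge))
  }
  u <- dx * cos(o$theta) + dy * sin(o$theta)
  v <- -dx * sin(o$theta) + dy * cos(o$theta)
  if (o$kind == "ellipse") {
    rho <- sqrt((u / o$a)^2 + (v / o$b)^2)
    return(amp * .edgeProfile((rho - 1) * o$b, o$edge))
  }
  # blob: radius modulated by low-order Fourier terms
  r <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  R <- o$a
  for (k in seq_along(o$four$k))
    R <- R + o$a * o$four$ak[k] * cos(o$four$k[k] * phi + o$four$ph[k])
  amp * .edgeProfile(r - R, o$edge)
}

# Core renderer: sample the analytic scene at pixel centres. origin =
# stage position of the centre of pixel (0, 0); row index increases with
# +Y (yAxisSign = +1 frames).
.render <- function(slide, origin, nrow., ncol., ps, channels,
                    noise = TRUE, noiseSeed = NULL) {
  spec <- slide@spec
  X <- origin[1] + (seq_len(ncol.) - 1) * ps
  Y <- origin[2] + (seq_len(nrow.) - 1) * ps
  img <- array(spec@background, dim = c(nrow., ncol., length(channels)),
               dimnames = list(NULL, NULL, channels))
  x0 <- X[1] - ps / 2; x1 <- X[ncol.] + ps / 2
  y0 <- Y[1] - ps / 2; y1 <- Y[nrow.] + ps / 2
  for (o in slide@objects) {
    rad <- o$rEff + o$edge
    if (o$x + rad < x0 || o$x - rad > x1 || o$y + rad < y0 ||
        o$y - rad > y1) next
    ci <- which(X >= o$x - rad & X <= o$x + rad)
    ri <- which(Y >= o$y - rad & Y <= o$y + rad)
    if (!length(ci) || !length(ri)) next
    for (ch in channels) {
      f <- .objectField(o, ch, X[ci], Y[ri])
      if (!identical(f, 0)) img[ri, ci, ch] <- img[ri, ci, ch] + f
    }
  }
  if (noise && spec@noiseSd > 0) {
    if (is.null(noiseSeed)) noiseSeed <- spec@seed
    img <- img + .withSeed(noiseSeed,
      array(rnorm(length(img), 0, spec@noiseSd), dim = dim(img)))
    dimnames(img) <- list(NULL, NULL, channels)
  }
  img
}

#' Render an arbitrary stage region of a virtual slide
#'
#' Samples the analytic intensity function on a pixel grid covering
#' `bounds` at `pixelSize` - the reference against which stitched
#' mosaics and re-acquisitions are compared.
#'
#' @param slide a [VirtualSlide-class].
#' @param bounds stage rectangle `c(x, y, w, h)`, micrometres.
#' @param pixelSize micrometres per pixel.
#' @param channels channel subset (default: all).
#' @param noise add Gaussian read noise (default FALSE: the noiseless
#'   reference).
#' @param noiseSeed integer; defaults to the slide seed.
#' @return list with `image` (rows x cols x channels array) and `frame`
#'   (the [MosaicFrame-class] mapping it to the stage).
#' @export
renderRegion <- function(slide, bounds, pixelSize,
                         channels = slideChannels(slide), noise = FALSE,
                         noiseSeed = NULL) {
  bounds <- .asRect(bounds)
  nc <- max(1L, round(bounds[["w"]] / pixelSize))
  nr <- max(1L, round(bounds[["h"]] / pixelSize))
  origin <- c(bounds[["x"]] + pixelSize / 2, bounds[["y"]] + pixelSize / 2)
  img <- .render(slide, origin, nr, nc, pixelSize, channels, noise,
                 noiseSeed)
  list(image = img,
       frame = mosaicFrame(stagePoint(origin[1], origin[2]), pixelSize, 1))
}

#' Acquire an item on the virtual microscope
#'
#' Renders what the instrument would capture for one plan item at the
#' given settings: pixel size = effective field of view / image size,
#' Gaussian read noise seeded by (slide seed, item id) so re-acquisition
#' is reproducible. The optical centre sits at the stage request minus
#' the objective's paracentricity offset, so plans corrected with
#' [applyParacentricity()] come out centred. Only a single z-plane and
#' time point are rendered; z-stack and time-lapse parameters are plan
#' metadata and pass through untouched. An item whose centre lies
#' outside the slide extent raises an out-of-bounds error.
#'
#' @param slide a [VirtualSlide-class].
#' @param settings an [AcquisitionSettings-class] whose channels exist on
#'   the slide.
#' @param item a [SingleField-class] or [TileGrid-class].
#' @return for a single field, a list with `image`, `frame` and `id`;
#'   for a tile grid, a list of such lists, enabled tiles only, in
#'   serpentine order.
#' @export
acquire <- function(slide, settings, item) {
  stopifnot(is(slide, "VirtualSlide"), is(settings, "AcquisitionSettings"))
  if (is(item, "TileGrid")) {
    tp <- tilePositions(item)
    return(lapply(seq_len(nrow(tp)), function(i)
      .acquireField(slide, settings,
                    stagePoint(tp$cx[i], tp$cy[i]), tp$tile_id[i])))
  }
  stopifnot(is(item, "SingleField"))
  .acquireField(slide, settings, item@center, item@id)
}

.acquireField <- function(slide, settings, center, id) {
  ext <- slide@spec@extent
  if (center@x < 0 || center@x > ext[1] || center@y < 0 ||
      center@y > ext[2])
    .stopInvalid("out-of-bounds error: item '%s' centre (%.1f, %.1f) outside slide extent %g x %g um",
                 id, center@x, center@y, ext[1], ext[2])
  ps <- pixelSizeUm(settings)
  nr <- settings@imageHeight; nc <- settings@imageWidth
  chs <- settings@channels$name
  missing <- setdiff(chs, slideChannels(slide))
  if (length(missing))
    .stopInvalid("configuration error: channel '%s' not present on slide",
                 missing[1])
  # optical centre displaced by the objective's paracentricity offset
  trueCx <- center@x - settings@objective@paracentricityDx
  trueCy <- center@y - settings@objective@paracentricityDy
  originTrue <- c(trueCx - (nc - 1) / 2 * ps, trueCy - (nr - 1) / 2 * ps)
  img <- .render(slide, originTrue, nr, nc, ps, chs, noise = TRUE,
                 noiseSeed = .deriveSeed(slide@spec@seed, id))
  # the frame reports stage-request coordinates (what the instrument logs)
  originReq <- stagePoint(center@x - (nc - 1) / 2 * ps,
                          center@y - (nr - 1) / 2 * ps)
  list(image = img, frame = mosaicFrame(originReq, ps, 1), id = id)
}

#' Stitch acquired tiles into a mosaic by nominal positions
#'
#' Places every tile at its frame's nominal stage position (no
#' registration - the virtual stage is exact and the search mosaic is a
#' locator, not a quantitative image) and averages overlap strips
#' unweighted.
#'
#' @param tiles list of acquisitions as returned by [acquire()] on a
#'   [TileGrid-class].
#' @return list with `image` (array) and `frame` of the mosaic.
#' @export
stitchTiles <- function(tiles) {
  stopifnot(length(tiles) >= 1L)
  ps <- tiles[[1]]$frame@pixelSize
  chs <- dimnames(tiles[[1]]$image)[[3]]
  ox <- min(vapply(tiles, function(t) t$frame@origin@x, numeric(1)))
  oy <- min(vapply(tiles, function(t) t$frame@origin@y, numeric(1)))
  x1 <- max(vapply(tiles, function(t)
    t$frame@origin@x + (dim(t$image)[2] - 1) * ps, numeric(1)))
  y1 <- max(vapply(tiles, function(t)
    t$frame@origin@y + (dim(t$image)[1] - 1) * ps, numeric(1)))
  nc <- round((x1 - ox) / ps) + 1L
  nr <- round((y1 - oy) / ps) + 1L
  acc <- array(0, dim = c(nr, nc, length(chs)),
               dimnames = list(NULL, NULL, chs))
  cnt <- matrix(0, nr, nc)
  for (t in tiles) {
    c0 <- round((t$frame@origin@x - ox) / ps)
    r0 <- round((t$frame@origin@y - oy) / ps)
    rr <- r0 + seq_len(dim(t$image)[1])
    cc <- c0 + seq_len(dim(t$image)[2])
    acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] + t$image
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  cnt[cnt == 0] <- NA
  for (k in seq_along(chs)) acc[, , k] <- acc[, , k] / cnt
  list(image = acc, frame = mosaicFrame(stagePoint(ox, oy), ps, 1))
}

setMethod("show", "SyntheticSampleSpec", function(object) {
  cat(sprintf(
    "SyntheticSampleSpec '%s': %g x %g um, channels %s, noise sd %g, seed %d\n",
    object@kind, object@extent[1], object@extent[2],
    paste(object@channels, collapse = "/"), object@noiseSd, object@seed))
})

setMethod("show", "VirtualSlide", function(object) {
  cat(sprintf("VirtualSlide (%s): %d ground-truth object(s) on %g x %g um\n",
              object@spec@kind, nrow(object@groundTruth),
              object@spec@extent[1], object@spec@extent[2]))
  if (object@spec@kind == "ctc")
    cat(sprintf("  events: %d\n",
                sum(object@groundTruth$class == "event")))
})
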