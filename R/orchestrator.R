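# The three-step workflow engine: first scan -> analysis -> second scan,
# in automatic ("play") or stepwise mode, with stitching, logging and a
# savings report. All randomness flows from the slide seed, so a fixed
# template + seed yields byte-identical coordinate CSV and scan-job JSON
# artifacts across runs.

.newManifest <- function(template, outDir, seed, runId = "run") {
  new("RunManifest", runId = runId, template = template, outDir = outDir,
      seed = as.integer(seed),
      status = c(first_scan = "pending", analysis = "pending",
                 second_scan = "pending"),
      artifacts = list(),
      log = data.frame(step = character(), message = character(),
                       elapsed_s = numeric()),
      savings = NA_real_, state = new.env(parent = emptyenv()))
}

.logStep <- function(manifest, step, msg, t0) {
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest@log <- rbind(manifest@log,
                        data.frame(step = step, message = msg,
                                   elapsed_s = round(el, 3)))
  message(sprintf("[%s] %s (%.1fs)", step, msg, el))
  manifest
}

.slotSlides <- function(template, slides) {
  ids <- template@layout@slots$slot_id
  if (is(slides, "VirtualSlide")) {
    out <- list(slides)
    names(out) <- ids[1]
    return(out)
  }
  stopifnot(is.list(slides), !is.null(names(slides)))
  missing <- setdiff(names(slides), ids)
  if (length(missing))
    .stopInvalid("slides named for unknown slot(s): %s",
                 paste(missing, collapse = ", "))
  slides
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Ingest a directory of externally acquired tiles
#'
#' Reads a tile-position manifest (`manifest.json`: pixel size, channel
#' names and per-tile stage origins) plus the referenced TIFF files -
#' the path by which real first-scan data enters the engine in place of
#' the virtual microscope. Missing tile files raise an error listing
#' their ids.
#'
#' @param dir directory containing `manifest.json` and the tiles.
#' @return list of acquisitions suitable for [stitchTiles()].
#' @export
readTileDir <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp))
    .stopInvalid("tile directory '%s' lacks manifest.json", dir)
  m <- .readJSON(mp)
  for (f in c("pixel_size_um", "channels", "tiles"))
    if (is.null(m[[f]]))
      .stopInvalid("tile manifest validation: missing field '%s'", f)
  files <- vapply(m$tiles, function(t) t$file, character(1))
  ok <- file.exists(file.path(dir, files))
  if (!all(ok))
    .stopInvalid("missing tile file(s): %s",
                 paste(vapply(m$tiles[!ok], function(t) t$id, character(1)),
                       collapse = ", "))
  chs <- unlist(m$channels)
  lapply(m$tiles, function(t) {
    img <- tiff::readTIFF(file.path(dir, t$file))
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    dimnames(img) <- list(NULL, NULL, chs[seq_len(dim(img)[3])])
    list(image = img,
         frame = mosaicFrame(stagePoint(t$origin_x_um, t$origin_y_um),
                             m$pixel_size_um,
                             if (is.null(m$y_axis_sign)) 1 else m$y_axis_sign),
         id = t$id)
  })
}

#' Step 1: capture and stitch the search mosaic
#'
#' Plans the low-resolution search mosaic over each sample, acquires all
#' tiles on the virtual microscope (or ingests a tile directory), and
#' stitches them by nominal stage positions. Artifacts per slot: the
#' mosaic TIFF (intensities clipped to [0, 1]) and the frame JSON.
#'
#' @param template a [Template-class].
#' @param slides a [VirtualSlide-class] (first slot), a named list
#'   (slot id -> slide), or a tile-directory path for ingestion.
#' @param outDir run directory (created if needed).
#' @param seed run seed; defaults to the slide's own seed.
#' @param manifest an existing [RunManifest-class] to update.
#' @return the updated [RunManifest-class].
#' @export
runFirstScan <- function(template, slides, outDir = tempfile("run"),
                         seed = NULL, manifest = NULL) {
  stopifnot(is(template, "Template"))
  t0 <- Sys.time()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(manifest)) {
    if (is.null(seed))
      seed <- if (is(slides, "VirtualSlide")) slides@spec@seed else 0L
    manifest <- .newManifest(template, outDir, seed)
  }
  s1 <- template@firstScanSettings
  fov1 <- unname(effectiveFov(s1))
  slots <- list()
  if (is.character(slides)) {
    tiles <- readTileDir(slides)
    st <- stitchTiles(tiles)
    slotId <- template@layout@slots$slot_id[1]
    slots[[slotId]] <- list(mosaic = st$image, frame = st$frame,
                            slide = NULL,
                            bounds = rectUm(
                              st$frame@origin@x - st$frame@pixelSize / 2,
                              st$frame@origin@y - st$frame@pixelSize / 2,
                              dim(st$image)[2] * st$frame@pixelSize,
                              dim(st$image)[1] * st$frame@pixelSize))
  } else {
    perSlot <- .slotSlides(template, slides)
    for (slotId in names(perSlot)) {
      slide <- perSlot[[slotId]]
      bounds <- rectUm(0, 0, slide@spec@extent[1], slide@spec@extent[2])
      grid <- planSearchMosaic(bounds, fov1, template@firstOverlap,
                               id = paste0("search_", slotId))
      tiles <- acquire(slide, s1, grid)
      st <- stitchTiles(tiles)
      slots[[slotId]] <- list(mosaic = st$image, frame = st$frame,
                              slide = slide, bounds = bounds)
    }
  }
  for (slotId in names(slots)) {
    sl <- slots[[slotId]]
    mosaicPath <- file.path(outDir, sprintf("mosaic_%s.tif", slotId))
    framePath <- file.path(outDir, sprintf("frame_%s.json", slotId))
    tiff::writeTIFF(.clip01(sl$mosaic), mosaicPath, bits.per.sample = 32L,
                    reduce = FALSE)
    writeFrame(sl$frame, framePath, dim = dim(sl$mosaic)[1:2])
    manifest@artifacts[[sprintf("mosaic_%s", slotId)]] <- mosaicPath
    manifest@artifacts[[sprintf("frame_%s", slotId)]] <- framePath
  }
  manifest@state$slots <- slots
  manifest@status[["first_scan"]] <- "done"
  .logStep(manifest, "first_scan",
           sprintf("%d slot(s) stitched", length(slots)), t0)
}

.builtinMacro <- function(template, macro, sl, records) {
  switch(macro,
    tissue = detectTissue(sl$mosaic, sl$frame, template@detectionParams),
    rare_events = detectRareEvents(sl$mosaic, sl$frame,
                                   template@detectionParams,
                                   template@markerRules),
    manual = importManualSelection(records, sl$frame),
    .stopInvalid("unknown macro '%s'", macro))
}

#' Step 2: locate the objects of interest
#'
#' Runs the chosen analysis macro on each stitched search mosaic:
#' built-in tissue or rare-event detection, an external macro through
#' the coordinate-list contract, or a manual selection. Nearby objects
#' are merged when the template requests it; the combined coordinate
#' list is written as the canonical CSV artifact.
#'
#' @param manifest a [RunManifest-class] with the first scan done.
#' @param macro override the template macro choice.
#' @param records manual-selection records (for `macro = "manual"`).
#' @return the updated [RunManifest-class].
#' @export
runAnalysis <- function(manifest, macro = NULL, records = NULL) {
  stopifnot(is(manifest, "RunManifest"))
  if (!identical(manifest@status[["first_scan"]], "done"))
    .stopInvalid("step order violation: first scan is '%s'",
                 manifest@status[["first_scan"]])
  t0 <- Sys.time()
  template <- manifest@template
  macro <- macro %||% template@macro
  slots <- manifest@state$slots
  multi <- length(slots) > 1L
  allObjects <- list()
  for (slotId in names(slots)) {
    sl <- slots[[slotId]]
    objs <- if (identical(macro, "external")) {
      parts <- strsplit(template@externalCommand, " +")[[1]]
      recs <- runExternalMacro(parts[1], parts[-1],
        manifest@artifacts[[sprintf("mosaic_%s", slotId)]],
        manifest@artifacts[[sprintf("frame_%s", slotId)]],
        file.path(manifest@outDir, sprintf("macro_out_%s.csv", slotId)))
      importManualSelection(recs, sl$frame)
    } else .builtinMacro(template, macro, sl, records)
    if (template@minSeparationUm > 0)
      objs <- mergeNearbyObjects(objs, template@minSeparationUm)
    if (multi)
      objs <- lapply(objs, function(o) {
        o@objectId <- paste(slotId, o@objectId, sep = "_"); o
      })
    slots[[slotId]]$objects <- objs
    allObjects <- c(allObjects, objs)
  }
  manifest@state$slots <- slots
  csvPath <- file.path(manifest@outDir, "coordinates.csv")
  writeCoordinates(objectsToRecords(allObjects), csvPath)
  manifest@artifacts$coordinates <- csvPath
  manifest@status[["analysis"]] <- "done"
  .logStep(manifest, "analysis",
           sprintf("%d object(s) via macro '%s'", length(allObjects), macro),
           t0)
}

#' Step 3: plan and acquire the high-resolution second scan
#'
#' For every detected object, builds a single field (small objects) or a
#' tile grid (large ones), prunes non-informative tiles when NoIR is
#' active, applies the paracentricity correction for the objective
#' change, acquires every enabled field at the second-scan settings and
#' writes the scan-job JSON per slot. An empty object list produces a
#' warning and no acquisition. The manifest's `savings` slot reports the
#' fraction of fields skipped relative to a full mosaic of the searched
#' area at the second-scan field of view.
#'
#' @param manifest a [RunManifest-class] with the analysis done.
#' @param noir override the template's NoIR flag.
#' @param writeImages write each acquired field as a TIFF under
#'   `images/<slot>/` (default TRUE).
#' @return the updated [RunManifest-class].
#' @export
runSecondScan <- function(manifest, noir = NULL, writeImages = TRUE) {
  stopifnot(is(manifest, "RunManifest"))
  if (!identical(manifest@status[["analysis"]], "done"))
    .stopInvalid("step order violation: analysis is '%s'",
                 manifest@status[["analysis"]])
  t0 <- Sys.time()
  template <- manifest@template
  noir <- noir %||% template@noirEnabled
  s1 <- template@firstScanSettings
  s2 <- template@secondScanSettings
  delta <- c(s2@objective@paracentricityDx - s1@objective@paracentricityDx,
             s2@objective@paracentricityDy - s1@objective@paracentricityDy)
  slots <- manifest@state$slots
  totEnabled <- 0; totFull <- 0; nAcq <- 0
  for (slotId in names(slots)) {
    sl <- slots[[slotId]]
    objs <- sl$objects
    if (length(objs) == 0L) {
      warning(sprintf("slot '%s': empty coordinate list; no acquisition",
                      slotId))
      next
    }
    plan <- planSecondScan(objs, s2, overlap = template@secondOverlap,
                           margin = template@planMarginUm)
    if (noir) {
      for (k in seq_along(plan@entries)) {
        e <- plan@entries[[k]]
        if (is(e, "TileGrid") && nrow(objs[[k]]@mask) > 0)
          plan@entries[[k]] <- applyNoir(e, objs[[k]]@mask, sl$frame,
                                         template@noirMarginUm,
                                         objs[[k]]@maskOffset)
      }
    }
    # paracentricity: express plan in second-objective stage requests
    items <- lapply(plan@entries, .shiftItem, dx = delta[1], dy = delta[2])
    job <- scanJob(s2, unname(items), sampleId = slotId)
    jobPath <- file.path(manifest@outDir,
                         sprintf("second_scan_job_%s.json", slotId))
    writeScanJob(job, jobPath)
    manifest@artifacts[[sprintf("second_scan_job_%s", slotId)]] <- jobPath
    if (!is.null(sl$slide)) {
      imgDir <- file.path(manifest@outDir, "images", slotId)
      if (writeImages) dir.create(imgDir, recursive = TRUE,
                                  showWarnings = FALSE)
      acqs <- list()
      for (it in items) {
        a <- acquire(sl$slide, s2, it)
        a <- if (is(it, "SingleField")) list(a) else a
        for (x in a) {
          nAcq <- nAcq + 1
          if (writeImages)
            tiff::writeTIFF(.clip01(x$image),
                            file.path(imgDir, paste0(x$id, ".tif")),
                            bits.per.sample = 32L, reduce = FALSE)
        }
        acqs <- c(acqs, a)
      }
      slots[[slotId]]$acquisitions <- acqs
    }
    slots[[slotId]]$plan <- plan
    totEnabled <- totEnabled + .planEnabledCount(plan)
    full <- planSearchMosaic(sl$bounds, plan@fov, plan@overlap)
    totFull <- totFull + length(full@rowCenters) * length(full@colCenters)
  }
  manifest@state$slots <- slots
  manifest@savings <- if (totFull > 0) max(0, min(1, 1 - totEnabled / totFull))
                      else NA_real_
  manifest@status[["second_scan"]] <- "done"
  .logStep(manifest, "second_scan",
           sprintf("%d field(s) acquired, savings %.3f", nAcq,
                   manifest@savings), t0)
}

#' Run the whole screening workflow ("play")
#'
#' Chains the three steps exactly as running them individually would:
#' identical seeds, bitwise-identical artifacts. A failure in one step
#' halts the chain.
#'
#' @inheritParams runFirstScan
#' @param noir override the template NoIR flag.
#' @param writeImages write second-scan field TIFFs.
#' @return the completed [RunManifest-class].
#' @examples
#' \donttest{
#' slide <- generateSlide(tmaSpec(nPieces = 4, extent = c(3000, 3000),
#'                                seed = 2))
#' tpl <- demoTemplate("tma")
#' m <- runAll(tpl, slide, outDir = tempfile("run"))
#' manifestStatus(m)
#' }
#' @export
runAll <- function(template, slides, outDir = tempfile("run"), seed = NULL,
                   noir = NULL, writeImages = TRUE) {
  m <- runFirstScan(template, slides, outDir, seed)
  m <- runAnalysis(m)
  runSecondScan(m, noir = noir, writeImages = writeImages)
}

#' Manifest accessors
#'
#' @param manifest a [RunManifest-class].
#' @return `manifestStatus`: named status vector; `manifestArtifacts`:
#'   named list of artifact paths; `manifestSavings`: fraction of
#'   second-scan fields skipped.
#' @export
manifestStatus <- function(manifest) manifest@status

#' @rdname manifestStatus
#' @export
manifestArtifacts <- function(manifest) manifest@artifacts

#' @rdname manifestStatus
#' @export
manifestSavings <- function(manifest) manifest@savings

#' Write the run manifest as JSON
#'
#' Serializes the light part of a manifest (status, artifacts, savings,
#' timing log); in-memory state is not persisted.
#'
#' @param manifest a [RunManifest-class].
#' @param sink file path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, sink) {
  .writeCanonicalJSON(list(
    schema_version = .SETTINGS_SCHEMA_VERSION,
    run_id = manifest@runId, seed = as.numeric(manifest@seed),
    status = as.list(manifest@status),
    artifacts = lapply(manifest@artifacts, identity),
    savings = if (is.na(manifest@savings)) NULL else manifest@savings,
    log = lapply(seq_len(nrow(manifest@log)), function(i)
      list(step = manifest@log$step[i], message = manifest@log$message[i],
           elapsed_s = manifest@log$elapsed_s[i]))), sink)
}

#' Ready-made demo template
#'
#' A small, fully specified [Template-class] for each built-in scenario,
#' used by the examples, the command-line interface and the test suite.
#' The first scan uses a 10x reference objective (zero paracentricity)
#' at coarse pixel size; the second scan uses a 40x objective with a
#' nonzero paracentricity offset.
#'
#' @param kind "tma" or "ctc".
#' @param extent slide extent `c(w, h)` the simulation block records.
#' @return a [Template-class].
#' @export
demoTemplate <- function(kind = c("tma", "ctc"), extent = NULL) {
  kind <- match.arg(kind)
  obj10 <- objectiveProfile("10x", 10, 2500, 2500)
  obj40 <- objectiveProfile("40x", 40, 250, 250, paracentricityDx = 4,
                            paracentricityDy = -3)
  if (kind == "tma") {
    extent <- extent %||% c(10000, 10000)
    s1 <- acquisitionSettings("tma_first", obj10, zoom = 1,
                              imageWidth = 512, imageHeight = 512,
                              channels = c(tissue = 1))
    s2 <- acquisitionSettings("tma_second", obj40, zoom = 1,
                              imageWidth = 256, imageHeight = 256,
                              channels = c(tissue = 1),
                              zStack = c(n_slices = 5, step_um = 1))
    screenTemplate(s1, s2,
                   # smallest expected piece is 200 um across (~3.1e4 um^2);
                   # the window spans half that to twice the largest piece
                   detectionParams("tissue", smoothingSigma = 1,
                                   minArea = 15000, maxArea = 1e6),
                   macro = "tissue", noirEnabled = TRUE, noirMarginUm = 10,
                   planMarginUm = 10, firstOverlap = 0.1,
                   secondOverlap = 0.1, minSeparationUm = 0,
                   layout = sampleLayout(data.frame(
                     slot_id = "slide1", x = 0, y = 0,
                     w = extent[1], h = extent[2])),
                   simulation = list(kind = "tma",
                                     extent_um = as.list(extent)))
  } else {
    extent <- extent %||% c(3000, 3000)
    s1 <- acquisitionSettings("ctc_first", obj10, zoom = 1,
                              imageWidth = 1250, imageHeight = 1250,
                              channels = c(dapi = 1, ck = 1, cd45 = 1))
    s2 <- acquisitionSettings("ctc_second", obj40, zoom = 1,
                              imageWidth = 256, imageHeight = 256,
                              channels = c(dapi = 1, ck = 1, cd45 = 1))
    screenTemplate(s1, s2,
                   detectionParams("dapi", smoothingSigma = 1,
                                   minArea = 20, maxArea = 1000),
                   macro = "rare_events",
                   markerRules = list(markerRule("ck", "positive", 0.35),
                                      markerRule("cd45", "negative", 0.35)),
                   noirEnabled = FALSE, planMarginUm = 5,
                   firstOverlap = 0, secondOverlap = 0,
                   layout = sampleLayout(data.frame(
                     slot_id = "slide1", x = 0, y = 0,
                     w = extent[1], h = extent[2])),
                   simulation = list(kind = "ctc",
                                     extent_um = as.list(extent)))
  }
}

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest '%s' (seed %d): %s\n", object@runId, object@seed,
              paste(sprintf("%s=%s", names(object@status), object@status),
                    collapse = ", ")))
  if (!is.na(object@savings))
    cat(sprintf("  savings: %.3f\n", object@savings))
})
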