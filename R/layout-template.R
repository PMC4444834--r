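# Sample layouts, experiment templates and scan jobs - the reloadable
# two-file workflow the engine edits and regenerates.

#' Create a sample layout
#'
#' @param slots data.frame with columns `slot_id`, `x`, `y`, `w`, `h`
#'   (min corner + size, micrometres). Slots must not overlap; at most
#'   five slots when `adapterKind` is `"slides"`.
#' @param adapterKind free text: "slides", "plate", "dish", ...
#' @return a [SampleLayout-class].
#' @examples
#' slideLayout(2, width = 20000, height = 10000)
#' @export
sampleLayout <- function(slots, adapterKind = "slides") {
  new("SampleLayout", slots = slots, adapterKind = adapterKind)
}

#' @rdname sampleLayout
#' @param n number of parallel slides (1-5).
#' @param width,height slide scan area, micrometres.
#' @param pitch spacing between slide origins, micrometres.
#' @export
slideLayout <- function(n = 1, width = 20000, height = 10000,
                        pitch = height + 5000) {
  stopifnot(n >= 1, n <= 5)
  sampleLayout(data.frame(slot_id = sprintf("slide%d", seq_len(n)),
                          x = 0, y = (seq_len(n) - 1) * pitch,
                          w = width, h = height),
               adapterKind = "slides")
}

#' Create an experiment template
#'
#' Bundles the two scan settings, the detection macro and parameters,
#' NoIR and planning options and the sample layout; templates can be
#' saved and reloaded ([saveTemplate()], [loadTemplate()]) so further
#' experiments reuse the whole definition.
#'
#' @param firstScanSettings,secondScanSettings [AcquisitionSettings-class]
#'   objects (stored as two independent settings files on save).
#' @param detectionParams [DetectionParams-class] for the built-in macros
#'   (the nucleus channel parameters for `macro = "rare_events"`).
#' @param macro "tissue", "rare_events", "external" or "manual".
#' @param markerRules list of [MarkerRule-class] (rare-event macro).
#' @param externalCommand command for the external-macro contract.
#' @param noirEnabled activate NoIR pruning of non-informative tiles.
#' @param noirMarginUm NoIR mask dilation margin, micrometres.
#' @param planMarginUm context margin around object boxes when planning.
#' @param firstOverlap,secondOverlap mosaic overlap fractions in [0, 0.9].
#' @param minSeparationUm merge objects closer than this before planning
#'   (0 disables).
#' @param layout a [SampleLayout-class].
#' @param simulation optional list describing a virtual slide for the
#'   command-line workflow (see [tmaSpec()] / [ctcSpec()]).
#' @param firstScanPath,secondScanPath settings file references recorded
#'   in the saved template (filled by [saveTemplate()]).
#' @return a [Template-class].
#' @export
screenTemplate <- function(firstScanSettings, secondScanSettings,
                           detectionParams, macro = "tissue",
                           markerRules = list(), externalCommand = "",
                           noirEnabled = FALSE, noirMarginUm = 0,
                           planMarginUm = 0, firstOverlap = 0.1,
                           secondOverlap = 0, minSeparationUm = 0,
                           layout = slideLayout(1),
                           simulation = list(),
                           firstScanPath = "first_scan_settings.json",
                           secondScanPath = "second_scan_settings.json") {
  new("Template", firstScanSettings = firstScanSettings,
      secondScanSettings = secondScanSettings,
      firstScanPath = firstScanPath, secondScanPath = secondScanPath,
      macro = macro, detectionParams = detectionParams,
      markerRules = markerRules, externalCommand = externalCommand,
      noirEnabled = noirEnabled, noirMarginUm = as.numeric(noirMarginUm),
      planMarginUm = as.numeric(planMarginUm),
      firstOverlap = as.numeric(firstOverlap),
      secondOverlap = as.numeric(secondOverlap),
      minSeparationUm = as.numeric(minSeparationUm), layout = layout,
      simulation = simulation)
}

.paramsToList <- function(p) {
  list(channel = p@channel, threshold_mode = p@thresholdMode,
       threshold_value = if (is.finite(p@thresholdValue))
         p@thresholdValue else NULL,
       smoothing_sigma = p@smoothingSigma, min_area_um2 = p@minArea,
       max_area_um2 = if (is.finite(p@maxArea)) p@maxArea else NULL)
}

.paramsFromList <- function(x) {
  for (f in c("channel", "threshold_mode", "smoothing_sigma", "min_area_um2"))
    if (is.null(x[[f]]))
      .stopInvalid("template validation: missing field 'detection_params.%s'", f)
  detectionParams(channel = x$channel, thresholdMode = x$threshold_mode,
                  thresholdValue = if (is.null(x$threshold_value)) NA_real_
                                   else x$threshold_value,
                  smoothingSigma = x$smoothing_sigma,
                  minArea = x$min_area_um2,
                  maxArea = if (is.null(x$max_area_um2)) Inf else x$max_area_um2)
}

.layoutToList <- function(l) {
  list(adapter_kind = l@adapterKind,
       slots = lapply(seq_len(nrow(l@slots)), function(i)
         list(slot_id = l@slots$slot_id[i], x_um = l@slots$x[i],
              y_um = l@slots$y[i], w_um = l@slots$w[i],
              h_um = l@slots$h[i])))
}

.layoutFromList <- function(x) {
  if (is.null(x$slots) || length(x$slots) == 0L)
    .stopInvalid("template validation: missing field 'layout.slots'")
  s <- do.call(rbind, lapply(x$slots, function(sl)
    data.frame(slot_id = sl$slot_id, x = sl$x_um, y = sl$y_um,
               w = sl$w_um, h = sl$h_um)))
  sampleLayout(s, adapterKind = x$adapter_kind %||% "slides")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load an experiment template
#'
#' The template document stores the two settings files by reference
#' (paths relative to the template file); `saveTemplate` writes both
#' settings documents next to the template, `loadTemplate` re-reads and
#' re-validates them. A dangling settings reference raises a resolution
#' error. Round-trips are canonical and byte-identical.
#'
#' @param t a [Template-class].
#' @param sink,source template file path.
#' @return `loadTemplate` the [Template-class]; `saveTemplate` the path,
#'   invisibly.
#' @export
saveTemplate <- function(t, sink) {
  stopifnot(is(t, "Template"))
  validObject(t)
  dir <- dirname(sink)
  writeSettings(t@firstScanSettings, file.path(dir, t@firstScanPath))
  writeSettings(t@secondScanSettings, file.path(dir, t@secondScanPath))
  doc <- list(schema_version = .SETTINGS_SCHEMA_VERSION,
              first_scan_settings = t@firstScanPath,
              second_scan_settings = t@secondScanPath,
              macro = t@macro,
              detection_params = .paramsToList(t@detectionParams),
              marker_rules = lapply(t@markerRules, function(r)
                list(channel = r@channel, polarity = r@polarity,
                     threshold = r@threshold)),
              external_command = if (nzchar(t@externalCommand))
                t@externalCommand else NULL,
              noir_enabled = t@noirEnabled,
              noir_margin_um = t@noirMarginUm,
              plan_margin_um = t@planMarginUm,
              first_overlap = t@firstOverlap,
              second_overlap = t@secondOverlap,
              min_separation_um = t@minSeparationUm,
              layout = .layoutToList(t@layout),
              simulation = if (length(t@simulation)) t@simulation else NULL)
  .writeCanonicalJSON(doc, sink)
}

#' @rdname saveTemplate
#' @export
loadTemplate <- function(source) {
  x <- .readJSON(source)
  .checkSchemaVersion(x, "template")
  for (f in c("first_scan_settings", "second_scan_settings", "macro",
              "detection_params", "layout"))
    if (is.null(x[[f]]))
      .stopInvalid("template validation: missing field '%s'", f)
  dir <- dirname(source)
  resolve <- function(ref, what) {
    p <- if (startsWith(ref, "/")) ref else file.path(dir, ref)
    if (!file.exists(p))
      .stopInvalid("template resolution error: %s '%s' not found", what, ref)
    p
  }
  first <- readSettings(resolve(x$first_scan_settings, "first_scan_settings"))
  second <- readSettings(resolve(x$second_scan_settings,
                                 "second_scan_settings"))
  rules <- lapply(x$marker_rules %||% list(), function(r)
    markerRule(r$channel, r$polarity, r$threshold))
  screenTemplate(first, second, .paramsFromList(x$detection_params),
                 macro = x$macro, markerRules = rules,
                 externalCommand = x$external_command %||% "",
                 noirEnabled = isTRUE(x$noir_enabled),
                 noirMarginUm = x$noir_margin_um %||% 0,
                 planMarginUm = x$plan_margin_um %||% 0,
                 firstOverlap = x$first_overlap %||% 0.1,
                 secondOverlap = x$second_overlap %||% 0,
                 minSeparationUm = x$min_separation_um %||% 0,
                 layout = .layoutFromList(x$layout),
                 simulation = x$simulation %||% list(),
                 firstScanPath = x$first_scan_settings,
                 secondScanPath = x$second_scan_settings)
}

# --- scan jobs ---

#' Create a scan job
#'
#' @param settings an [AcquisitionSettings-class].
#' @param items list of [SingleField-class] / [TileGrid-class].
#' @param sampleId slot id of the sample the items belong to.
#' @return a [ScanJob-class].
#' @export
scanJob <- function(settings, items, sampleId = "slide1") {
  new("ScanJob", settings = settings, items = items, sampleId = sampleId)
}

.itemToList <- function(it) {
  if (is(it, "SingleField"))
    return(list(type = "single_field", id = it@id,
                center_x_um = it@center@x, center_y_um = it@center@y,
                width_um = it@width, height_um = it@height))
  list(type = "tile_grid", id = it@id, tile_w_um = it@tileW,
       tile_h_um = it@tileH, overlap = it@overlap,
       col_centers_um = as.list(it@colCenters),
       row_centers_um = as.list(it@rowCenters),
       enabled = lapply(seq_len(nrow(it@enabled)), function(r)
         as.list(unname(it@enabled[r, ]))),
       order = "serpentine")
}

.itemFromList <- function(x) {
  if (identical(x$type, "single_field"))
    return(singleField(stagePoint(x$center_x_um, x$center_y_um),
                       x$width_um, x$height_um, id = x$id))
  if (identical(x$type, "tile_grid")) {
    en <- do.call(rbind, lapply(x$enabled, function(r)
      vapply(r, isTRUE, logical(1))))
    return(new("TileGrid", id = x$id, tileW = x$tile_w_um,
               tileH = x$tile_h_um, overlap = x$overlap,
               colCenters = vapply(x$col_centers_um, as.numeric, numeric(1)),
               rowCenters = vapply(x$row_centers_um, as.numeric, numeric(1)),
               enabled = en))
  }
  .stopInvalid("scan job validation: unknown item type '%s'", x$type)
}

#' Read / write scan-job files
#'
#' A scan job is the second machine-loadable file of the workflow: the
#' full settings document plus the list of positions (single fields and
#' tile grids, with their NoIR enable masks) to acquire. Canonical JSON;
#' round-trips byte-identically.
#'
#' @param job a [ScanJob-class].
#' @param sink,source file path.
#' @return `readScanJob` the job; `writeScanJob` the path, invisibly.
#' @export
writeScanJob <- function(job, sink) {
  stopifnot(is(job, "ScanJob"))
  validObject(job)
  .writeCanonicalJSON(list(schema_version = .SETTINGS_SCHEMA_VERSION,
                           sample_id = job@sampleId,
                           settings = .settingsToList(job@settings),
                           items = lapply(job@items, .itemToList)), sink)
}

#' @rdname writeScanJob
#' @export
readScanJob <- function(source) {
  x <- .readJSON(source)
  .checkSchemaVersion(x, "scan job")
  for (f in c("sample_id", "settings", "items"))
    if (is.null(x[[f]]))
      .stopInvalid("scan job validation: missing field '%s'", f)
  scanJob(.settingsFromList(x$settings), lapply(x$items, .itemFromList),
          sampleId = x$sample_id)
}

#' Validate a scan job against a sample layout
#'
#' A job is valid when every single-field centre and every enabled tile
#' centre lies inside the bounds of the job's sample slot.
#'
#' @param job a [ScanJob-class].
#' @param layout a [SampleLayout-class].
#' @return character vector of violations (empty when valid), each naming
#'   the offending item.
#' @export
validateJob <- function(job, layout) {
  stopifnot(is(job, "ScanJob"), is(layout, "SampleLayout"))
  s <- layout@slots
  i <- match(job@sampleId, s$slot_id)
  if (is.na(i))
    return(sprintf("sample '%s' not present in layout", job@sampleId))
  x0 <- s$x[i]; y0 <- s$y[i]; x1 <- x0 + s$w[i]; y1 <- y0 + s$h[i]
  bad <- character()
  inside <- function(x, y) x >= x0 & x <= x1 & y >= y0 & y <= y1
  for (it in job@items) {
    if (is(it, "SingleField")) {
      if (!inside(it@center@x, it@center@y))
        bad <- c(bad, sprintf("item '%s': field centre outside slot '%s'",
                              it@id, job@sampleId))
    } else {
      tp <- tilePositions(it)
      if (nrow(tp) && !all(inside(tp$cx, tp$cy)))
        bad <- c(bad, sprintf("item '%s': %d tile centre(s) outside slot '%s'",
                              it@id, sum(!inside(tp$cx, tp$cy)), job@sampleId))
    }
  }
  bad
}

setMethod("show", "Template", function(object) {
  cat(sprintf(
    "Template: macro '%s', NoIR %s (margin %g um), %d sample slot(s)\n",
    object@macro, if (object@noirEnabled) "on" else "off",
    object@noirMarginUm, nrow(object@layout@slots)))
  cat(sprintf("  first scan:  %s\n", object@firstScanSettings@id))
  cat(sprintf("  second scan: %s\n", object@secondScanSettings@id))
})

setMethod("show", "ScanJob", function(object) {
  n1 <- sum(vapply(object@items, is, logical(1), "SingleField"))
  cat(sprintf("ScanJob [%s, sample %s]: %d single field(s), %d tile grid(s)\n",
              object@settings@id, object@sampleId, n1,
              length(object@items) - n1))
})
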