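#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

.finiteNum <- function(x) is.numeric(x) && all(is.finite(x))

#' StagePoint: physical stage coordinates
#'
#' A (possibly vectorized) point on the microscope stage, in micrometres.
#' X increases rightward; the direction of Y relative to image rows is a
#' property of the [MosaicFrame-class], not of the point.
#'
#' @slot x,y numeric vectors of equal length, micrometres.
#' @exportClass StagePoint
setClass("StagePoint", representation(x = "numeric", y = "numeric"),
  validity = function(object) {
    if (length(object@x) != length(object@y))
      return("x and y must have equal length")
    if (!.finiteNum(object@x) || !.finiteNum(object@y))
      return("stage coordinates must be finite numbers")
    TRUE
  })

#' ObjectiveProfile: objective lens description
#'
#' Field of view at zoom 1 and the paracentricity offset of the optical
#' centre relative to a declared reference objective (for which the offset
#' is (0, 0) by convention). Changing objectives between the search scan
#' and the re-acquisition scan shifts the optical centre by the difference
#' of the two offsets; [applyParacentricity()] compensates for it.
#'
#' @slot name identifier.
#' @slot magnification dimensionless, > 0.
#' @slot fovWidth,fovHeight field of view at zoom 1, micrometres, > 0.
#' @slot paracentricityDx,paracentricityDy offset of the optical centre
#'   relative to the reference objective, micrometres.
#' @exportClass ObjectiveProfile
setClass("ObjectiveProfile",
  representation(name = "character", magnification = "numeric",
    fovWidth = "numeric", fovHeight = "numeric",
    paracentricityDx = "numeric", paracentricityDy = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    for (s in c("magnification", "fovWidth", "fovHeight"))
      if (!isTRUE(slot(object, s) > 0))
        return(sprintf("%s must be a single positive number", s))
    if (!.finiteNum(object@paracentricityDx) ||
        !.finiteNum(object@paracentricityDy))
      return("paracentricity offsets must be finite")
    TRUE
  })

#' MosaicFrame: affine link between mosaic pixels and the stage
#'
#' Pixel indices are 0-based and refer to pixel centres; the origin is the
#' stage position of the centre of pixel (col = 0, row = 0). `yAxisSign`
#' records whether the pixel row index increases with stage Y (+1) or
#' against it (-1), which differs between vendors.
#'
#' @slot origin [StagePoint-class] of the centre of pixel (0, 0).
#' @slot pixelSize micrometres per pixel, > 0.
#' @slot yAxisSign +1 or -1.
#' @exportClass MosaicFrame
setClass("MosaicFrame",
  representation(origin = "StagePoint", pixelSize = "numeric",
    yAxisSign = "numeric"),
  validity = function(object) {
    if (length(object@origin@x) != 1L) return("origin must be a single point")
    if (!isTRUE(object@pixelSize > 0)) return("pixelSize must be > 0")
    if (!object@yAxisSign %in% c(1, -1)) return("yAxisSign must be +1 or -1")
    TRUE
  })

#' AcquisitionSettings: imaging parameters for one scan
#'
#' The machine-editable parameter set of one acquisition: objective, zoom,
#' image geometry, channels, z-stack and time-lapse. The effective field of
#' view is the objective field of view divided by zoom. Serialized to the
#' versioned JSON settings dialect by [writeSettings()].
#'
#' @slot id settings identifier.
#' @slot objective an [ObjectiveProfile-class].
#' @slot zoom dimensionless, >= 1.
#' @slot imageWidth,imageHeight pixels, >= 1.
#' @slot channels data.frame with columns `name` (character) and
#'   `exposure` (numeric > 0, exposure or gain in instrument units).
#' @slot zStack named numeric `c(n_slices, step_um)`; n_slices >= 1, step >= 0.
#' @slot timeLapse named numeric `c(n_frames, interval_s)`.
#' @exportClass AcquisitionSettings
setClass("AcquisitionSettings",
  representation(id = "character", objective = "ObjectiveProfile",
    zoom = "numeric", imageWidth = "integer", imageHeight = "integer",
    channels = "data.frame", zStack = "numeric", timeLapse = "numeric"),
  validity = function(object) {
    if (!isTRUE(object@zoom >= 1)) return("zoom must be >= 1")
    if (!isTRUE(object@imageWidth >= 1L) || !isTRUE(object@imageHeight >= 1L))
      return("image dimensions must be >= 1 pixel")
    if (!all(c("name", "exposure") %in% names(object@channels)) ||
        nrow(object@channels) < 1L)
      return("channels must have columns name, exposure and >= 1 row")
    if (anyDuplicated(object@channels$name))
      return("channel names must be unique")
    if (!identical(names(object@zStack), c("n_slices", "step_um")) ||
        object@zStack[["n_slices"]] < 1 || object@zStack[["step_um"]] < 0)
      return("zStack must be c(n_slices >= 1, step_um >= 0)")
    if (!identical(names(object@timeLapse), c("n_frames", "interval_s")) ||
        object@timeLapse[["n_frames"]] < 1 ||
        object@timeLapse[["interval_s"]] < 0)
      return("timeLapse must be c(n_frames >= 1, interval_s >= 0)")
    TRUE
  })

#' SingleField: one second-scan camera field
#'
#' @slot id item identifier.
#' @slot center [StagePoint-class] of the field centre.
#' @slot width,height micrometres (the second-scan effective field of view).
#' @exportClass SingleField
setClass("SingleField",
  representation(id = "character", center = "StagePoint",
    width = "numeric", height = "numeric"),
  validity = function(object) {
    if (!isTRUE(object@width > 0) || !isTRUE(object@height > 0))
      return("field dimensions must be > 0")
    TRUE
  })

#' TileGrid: overlap-aware field layout with per-tile enable mask
#'
#' Tile (row = 0, col = 0) is centred at (`colCenters[1]`, `rowCenters[1]`).
#' Inner tiles are spaced by `tile size * (1 - overlap)`; the last row and
#' column may be shifted inward so the grid never extends past the planned
#' bounds by more than half a field (see [planSearchMosaic()]). `enabled`
#' is the NoIR output: disabled tiles are planned but not acquired.
#' Acquisition order is row-major serpentine ([tilePositions()]).
#'
#' @slot id item identifier.
#' @slot tileW,tileH effective field of view of one tile, micrometres.
#' @slot overlap fraction in [0, 0.9].
#' @slot colCenters,rowCenters stage coordinates of tile centres (X for
#'   columns, Y for rows), micrometres.
#' @slot enabled logical matrix, rows x cols.
#' @exportClass TileGrid
setClass("TileGrid",
  representation(id = "character", tileW = "numeric", tileH = "numeric",
    overlap = "numeric", colCenters = "numeric", rowCenters = "numeric",
    enabled = "matrix"),
  validity = function(object) {
    if (!isTRUE(object@tileW > 0) || !isTRUE(object@tileH > 0))
      return("tile dimensions must be > 0")
    if (object@overlap < 0 || object@overlap > 0.9)
      return("overlap must be in [0, 0.9]")
    if (length(object@colCenters) < 1L || length(object@rowCenters) < 1L)
      return("grid must have >= 1 row and column")
    if (!is.logical(object@enabled) ||
        !identical(dim(object@enabled),
                   c(length(object@rowCenters), length(object@colCenters))))
      return("enabled must be a logical rows x cols matrix")
    TRUE
  })

#' SecondScanPlan: per-object high-resolution acquisition plan
#'
#' One entry per detected object: a [SingleField-class] when the padded
#' bounding box fits in one second-scan field, otherwise a
#' [TileGrid-class] covering it (optionally NoIR-pruned).
#'
#' @slot entries named list (object id -> SingleField | TileGrid).
#' @slot settingsId id of the second-scan [AcquisitionSettings-class].
#' @slot fov numeric `c(w, h)`: the second-scan effective field, micrometres.
#' @slot overlap tile overlap fraction used for grids.
#' @exportClass SecondScanPlan
setClass("SecondScanPlan",
  representation(entries = "list", settingsId = "character",
    fov = "numeric", overlap = "numeric"),
  validity = function(object) {
    if (length(object@entries) &&
        (is.null(names(object@entries)) || any(names(object@entries) == "")))
      return("entries must be named by object id")
    ok <- vapply(object@entries, function(e)
      is(e, "SingleField") || is(e, "TileGrid"), logical(1))
    if (!all(ok)) return("entries must be SingleField or TileGrid")
    TRUE
  })

#' SampleLayout: sample slots on the stage
#'
#' Physical positions of the mounted samples: up to five slides in
#' parallel, or the wells/dishes of another adapter. Slots must not
#' overlap.
#'
#' @slot slots data.frame with columns `slot_id`, `x`, `y`, `w`, `h`
#'   (min corner + size, micrometres).
#' @slot adapterKind free text ("slides", "plate", "dish", ...).
#' @exportClass SampleLayout
setClass("SampleLayout",
  representation(slots = "data.frame", adapterKind = "character"),
  validity = function(object) {
    s <- object@slots
    need <- c("slot_id", "x", "y", "w", "h")
    if (!all(need %in% names(s))) return("slots needs slot_id, x, y, w, h")
    if (nrow(s) < 1L) return("layout needs >= 1 slot")
    if (identical(object@adapterKind, "slides") && nrow(s) > 5L)
      return("at most 5 slide slots are supported")
    if (anyDuplicated(s$slot_id)) return("slot ids must be unique")
    if (any(s$w <= 0) || any(s$h <= 0)) return("slot sizes must be > 0")
    if (nrow(s) > 1L) {
      for (i in seq_len(nrow(s) - 1L)) for (j in (i + 1L):nrow(s)) {
        if (s$x[i] < s$x[j] + s$w[j] && s$x[j] < s$x[i] + s$w[i] &&
            s$y[i] < s$y[j] + s$h[j] && s$y[j] < s$y[i] + s$h[i])
          return(sprintf("slots %s and %s overlap", s$slot_id[i], s$slot_id[j]))
      }
    }
    TRUE
  })

#' ScanJob: settings plus the positions to acquire
#'
#' The content of one machine-loadable acquisition file: the imaging
#' parameters and the list of single fields or tile grids to visit, for
#' one sample slot.
#'
#' @slot settings [AcquisitionSettings-class].
#' @slot items list of [SingleField-class] / [TileGrid-class].
#' @slot sampleId slot id in the [SampleLayout-class].
#' @exportClass ScanJob
setClass("ScanJob",
  representation(settings = "AcquisitionSettings", items = "list",
    sampleId = "character"),
  validity = function(object) {
    ok <- vapply(object@items, function(e)
      is(e, "SingleField") || is(e, "TileGrid"), logical(1))
    if (!all(ok)) return("items must be SingleField or TileGrid")
    TRUE
  })

#' DetectionParams: the three tunable analysis parameters
#'
#' Threshold (fixed value or Otsu), Gaussian smoothing, and object size
#' filter - the minimal parameter triple of the built-in detection macros.
#'
#' @slot channel channel name the threshold applies to.
#' @slot thresholdMode "otsu" or "fixed".
#' @slot thresholdValue intensity cutoff (used when mode is "fixed").
#' @slot smoothingSigma Gaussian sigma in pixels, >= 0 (0 = no smoothing).
#' @slot minArea,maxArea object area window, square micrometres
#'   (`maxArea = Inf` for unbounded).
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(channel = "character", thresholdMode = "character",
    thresholdValue = "numeric", smoothingSigma = "numeric",
    minArea = "numeric", maxArea = "numeric"),
  validity = function(object) {
    if (!object@thresholdMode %in% c("otsu", "fixed"))
      return("thresholdMode must be 'otsu' or 'fixed'")
    if (identical(object@thresholdMode, "fixed") &&
        !.finiteNum(object@thresholdValue))
      return("fixed mode needs a finite thresholdValue")
    if (!isTRUE(object@smoothingSigma >= 0))
      return("smoothingSigma must be >= 0")
    if (!isTRUE(object@minArea >= 0)) return("minArea must be >= 0")
    if (!isTRUE(object@maxArea >= object@minArea))
      return("minArea must be <= maxArea")
    TRUE
  })

#' MarkerRule: one marker gate of the rare-event classifier
#'
#' A cell is an event iff every positive-polarity rule's mean intensity is
#' >= its threshold and every negative-polarity rule's mean is strictly
#' below its threshold (the classical nucleated CK+ / CD45- gate uses one
#' rule of each polarity).
#'
#' @slot channel marker channel name.
#' @slot polarity "positive" or "negative".
#' @slot threshold mean-intensity cutoff, >= 0.
#' @exportClass MarkerRule
setClass("MarkerRule",
  representation(channel = "character", polarity = "character",
    threshold = "numeric"),
  validity = function(object) {
    if (!object@polarity %in% c("positive", "negative"))
      return("polarity must be 'positive' or 'negative'")
    if (!isTRUE(object@threshold >= 0)) return("threshold must be >= 0")
    TRUE
  })

#' DetectedObject: one object of interest
#'
#' Centroid and bounding box in stage micrometres, the pixel mask in
#' mosaic space (cropped to the bounding box, with its 0-based pixel
#' offset), per-channel mean intensities, and a border flag for objects
#' touching the mosaic edge (kept, never dropped).
#'
#' @slot objectId identifier.
#' @slot label object class ("tissue", "event", "manual", ...).
#' @slot centroid [StagePoint-class], stage micrometres.
#' @slot bboxUm named numeric `c(x, y, w, h)`: min corner + size, stage um.
#' @slot areaUm2 mask area in square micrometres.
#' @slot channelStats named numeric, per-channel mean intensity.
#' @slot score detection score (classifier margin, or as given).
#' @slot mask logical matrix (rows x cols) in mosaic pixel space.
#' @slot maskOffset integer `c(col0, row0)`: 0-based mosaic pixel of
#'   `mask[1, 1]`.
#' @slot border TRUE if the object touches the mosaic border.
#' @exportClass DetectedObject
setClass("DetectedObject",
  representation(objectId = "character", label = "character",
    centroid = "StagePoint", bboxUm = "numeric", areaUm2 = "numeric",
    channelStats = "numeric", score = "numeric", mask = "matrix",
    maskOffset = "integer", border = "logical"),
  validity = function(object) {
    b <- object@bboxUm
    if (!identical(names(b), c("x", "y", "w", "h")))
      return("bboxUm must be named c(x, y, w, h)")
    if (b[["w"]] < 0 || b[["h"]] < 0) return("bbox dimensions must be >= 0")
    tol <- 1e-6 * max(1, b[["w"]], b[["h"]])
    if (object@centroid@x < b[["x"]] - tol ||
        object@centroid@x > b[["x"]] + b[["w"]] + tol ||
        object@centroid@y < b[["y"]] - tol ||
        object@centroid@y > b[["y"]] + b[["h"]] + tol)
      return("centroid must lie inside the bounding box")
    TRUE
  })

#' Template: a reloadable experiment definition
#'
#' Everything a screening run needs: the two independent settings files
#' (search scan and re-acquisition scan), the detection macro and its
#' parameters, NoIR options, planning margins and the sample layout.
#' Saved/loaded by [saveTemplate()] / [loadTemplate()].
#'
#' @slot firstScanSettings,secondScanSettings resolved
#'   [AcquisitionSettings-class].
#' @slot firstScanPath,secondScanPath the settings file references stored
#'   in the template document (resolved at load time).
#' @slot macro "tissue", "rare_events", "external" or "manual".
#' @slot detectionParams [DetectionParams-class] (nucleus params for the
#'   rare-event macro).
#' @slot markerRules list of [MarkerRule-class] (rare-event macro only).
#' @slot externalCommand command line for the external macro contract.
#' @slot noirEnabled logical; `noirMarginUm` the NoIR dilation margin (um).
#' @slot planMarginUm context margin added around object boxes when
#'   planning the second scan (um).
#' @slot firstOverlap,secondOverlap mosaic overlap fractions.
#' @slot minSeparationUm objects closer than this are merged before
#'   planning (0 disables merging).
#' @slot layout [SampleLayout-class].
#' @slot simulation list; optional virtual-slide description used by the
#'   command-line `simulate`/`play` verbs.
#' @exportClass Template
setClass("Template",
  representation(firstScanSettings = "AcquisitionSettings",
    secondScanSettings = "AcquisitionSettings",
    firstScanPath = "character", secondScanPath = "character",
    macro = "character", detectionParams = "DetectionParams",
    markerRules = "list", externalCommand = "character",
    noirEnabled = "logical", noirMarginUm = "numeric",
    planMarginUm = "numeric", firstOverlap = "numeric",
    secondOverlap = "numeric", minSeparationUm = "numeric",
    layout = "SampleLayout", simulation = "list"),
  validity = function(object) {
    if (!object@macro %in% c("tissue", "rare_events", "external", "manual"))
      return("macro must be tissue/rare_events/external/manual")
    if (!isTRUE(object@noirMarginUm >= 0) || !isTRUE(object@planMarginUm >= 0))
      return("margins must be >= 0")
    for (s in c("firstOverlap", "secondOverlap"))
      if (slot(object, s) < 0 || slot(object, s) > 0.9)
        return(sprintf("%s must be in [0, 0.9]", s))
    ok <- vapply(object@markerRules, is, logical(1), "MarkerRule")
    if (!all(ok)) return("markerRules must be MarkerRule objects")
    TRUE
  })

#' SyntheticSampleSpec: ground-truth scene description
#'
#' Parameters of a virtual slide: a tissue-microarray scene (`kind =
#' "tma"`: differently sized smooth tissue pieces) or a rare-event cell
#' field (`kind = "ctc"`: nucleated cells, a small fraction of which are
#' cytokeratin-positive / CD45-negative events). Fully determined by its
#' seed. See [tmaSpec()] and [ctcSpec()] for the parameter lists.
#'
#' @slot kind "tma" or "ctc".
#' @slot extent numeric `c(w, h)`, micrometres.
#' @slot channels channel names rendered for this kind.
#' @slot background background intensity (arbitrary units in [0, 1]).
#' @slot noiseSd additive Gaussian read-noise standard deviation.
#' @slot seed integer seed.
#' @slot params kind-specific parameter list.
#' @exportClass SyntheticSampleSpec
setClass("SyntheticSampleSpec",
  representation(kind = "character", extent = "numeric",
    channels = "character", background = "numeric", noiseSd = "numeric",
    seed = "integer", params = "list"),
  validity = function(object) {
    if (!object@kind %in% c("tma", "ctc")) return("kind must be tma or ctc")
    if (length(object@extent) != 2L || any(object@extent <= 0))
      return("extent must be two positive lengths")
    if (!isTRUE(object@noiseSd >= 0)) return("noiseSd must be >= 0")
    if (object@kind == "ctc") {
      f <- object@params$eventFraction
      if (is.null(f) || f < 0 || f > 1)
        return("eventFraction must be in [0, 1]")
    }
    TRUE
  })

#' VirtualSlide: a generated scene with ground truth
#'
#' The analytic intensity function (sum of smooth object profiles over a
#' uniform background) together with the ground-truth object table, so any
#' field at any pixel size can be rendered consistently and detection can
#' be scored exactly. Reproducible from (spec, seed).
#'
#' @slot spec the generating [SyntheticSampleSpec-class].
#' @slot groundTruth data.frame: one row per placed object (id, class,
#'   x, y, size and per-channel intensities).
#' @slot objects list of internal render descriptors.
#' @exportClass VirtualSlide
setClass("VirtualSlide",
  representation(spec = "SyntheticSampleSpec", groundTruth = "data.frame",
    objects = "list"))

#' RunManifest: state and artifacts of one screening run
#'
#' Tracks the three workflow steps (search scan, analysis, re-acquisition),
#' the artifact files written under the run directory, a timing log, and -
#' in a non-serialized state environment - the in-memory mosaics used by
#' later steps. Step N cannot complete before step N-1 (manual coordinate
#' injection may replace step 2).
#'
#' @slot runId identifier.
#' @slot template the [Template-class] in force.
#' @slot outDir run directory (artifacts live under it).
#' @slot seed integer run seed; all randomness derives from it.
#' @slot status named character: first_scan/analysis/second_scan ->
#'   pending/done/failed.
#' @slot artifacts named list of file paths.
#' @slot log data.frame(step, message, elapsed_s).
#' @slot savings fraction of second-scan fields skipped vs a full mosaic.
#' @slot state environment holding in-memory mosaics and objects.
#' @exportClass RunManifest
setClass("RunManifest",
  representation(runId = "character", template = "Template",
    outDir = "character", seed = "integer", status = "character",
    artifacts = "list", log = "data.frame", savings = "numeric",
    state = "environment"),
  validity = function(object) {
    need <- c("first_scan", "analysis", "second_scan")
    if (!all(need %in% names(object@status)))
      return("status must cover first_scan, analysis, second_scan")
    if (!all(object@status %in% c("pending", "done", "failed")))
      return("status values must be pending/done/failed")
    TRUE
  })
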