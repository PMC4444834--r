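# Acquisition-settings documents: the machine-editable JSON dialect that
# stands in for proprietary metadata files. One document per scan; the
# search scan and the re-acquisition scan are stored as two independent
# files.

.SETTINGS_SCHEMA_VERSION <- 1

#' Create acquisition settings
#'
#' @param id settings identifier.
#' @param objective an [ObjectiveProfile-class].
#' @param zoom dimensionless zoom, >= 1; the effective field of view is
#'   the objective field divided by zoom.
#' @param imageWidth,imageHeight image size in pixels.
#' @param channels data.frame with columns `name`, `exposure`, or a named
#'   numeric vector (names = channels, values = exposure/gain).
#' @param zStack numeric `c(n_slices, step_um)`.
#' @param timeLapse numeric `c(n_frames, interval_s)`.
#' @return an [AcquisitionSettings-class].
#' @examples
#' obj <- objectiveProfile("10x", 10, 1500, 1500)
#' acquisitionSettings("scan1", obj, imageWidth = 256, imageHeight = 256,
#'                     channels = c(dapi = 1))
#' @export
acquisitionSettings <- function(id, objective, zoom = 1,
                                imageWidth, imageHeight,
                                channels,
                                zStack = c(n_slices = 1, step_um = 0),
                                timeLapse = c(n_frames = 1, interval_s = 0)) {
  if (is.numeric(channels) && !is.null(names(channels)))
    channels <- data.frame(name = names(channels),
                           exposure = as.numeric(channels))
  zStack <- setNames(as.numeric(zStack), c("n_slices", "step_um"))
  timeLapse <- setNames(as.numeric(timeLapse), c("n_frames", "interval_s"))
  new("AcquisitionSettings", id = id, objective = objective,
      zoom = as.numeric(zoom), imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight), channels = channels,
      zStack = zStack, timeLapse = timeLapse)
}

#' Effective field of view and pixel size of a settings document
#'
#' `effectiveFov` returns `c(w, h)` = objective field of view / zoom, in
#' micrometres; `pixelSizeUm` divides by the image size in pixels and
#' requires square pixels (within 1e-9 um).
#'
#' @param settings an [AcquisitionSettings-class].
#' @return numeric `c(w, h)` or a single pixel size in micrometres.
#' @export
effectiveFov <- function(settings) {
  stopifnot(is(settings, "AcquisitionSettings"))
  c(w = settings@objective@fovWidth / settings@zoom,
    h = settings@objective@fovHeight / settings@zoom)
}

#' @rdname effectiveFov
#' @export
pixelSizeUm <- function(settings) {
  fov <- effectiveFov(settings)
  px <- fov[["w"]] / settings@imageWidth
  py <- fov[["h"]] / settings@imageHeight
  if (abs(px - py) > 1e-9)
    .stopInvalid("non-square pixels (%.6g x %.6g um); adjust zoom or image size",
                 px, py)
  px
}

.objectiveToList <- function(o) {
  list(name = o@name, magnification = o@magnification,
       fov_width_um = o@fovWidth, fov_height_um = o@fovHeight,
       paracentricity_dx_um = o@paracentricityDx,
       paracentricity_dy_um = o@paracentricityDy)
}

.objectiveFromList <- function(x, where = "objective") {
  for (f in c("name", "magnification", "fov_width_um", "fov_height_um",
              "paracentricity_dx_um", "paracentricity_dy_um"))
    if (is.null(x[[f]]))
      .stopInvalid("settings validation: missing field '%s.%s'", where, f)
  objectiveProfile(x$name, x$magnification, x$fov_width_um, x$fov_height_um,
                   x$paracentricity_dx_um, x$paracentricity_dy_um)
}

.settingsToList <- function(s) {
  list(schema_version = .SETTINGS_SCHEMA_VERSION,
       id = s@id,
       objective = .objectiveToList(s@objective),
       zoom = s@zoom,
       image_width = as.numeric(s@imageWidth),
       image_height = as.numeric(s@imageHeight),
       channels = lapply(seq_len(nrow(s@channels)), function(i)
         list(name = s@channels$name[i], exposure = s@channels$exposure[i])),
       z_stack = list(n_slices = s@zStack[["n_slices"]],
                      step_um = s@zStack[["step_um"]]),
       time_lapse = list(n_frames = s@timeLapse[["n_frames"]],
                         interval_s = s@timeLapse[["interval_s"]]))
}

.checkSchemaVersion <- function(x, what) {
  if (is.null(x$schema_version))
    .stopInvalid("%s validation: missing field 'schema_version'", what)
  if (!identical(as.numeric(x$schema_version),
                 as.numeric(.SETTINGS_SCHEMA_VERSION)))
    .stopInvalid("%s version error: unknown schema_version %s", what,
                 format(x$schema_version))
}

.settingsFromList <- function(x) {
  .checkSchemaVersion(x, "settings")
  for (f in c("id", "objective", "zoom", "image_width", "image_height",
              "channels", "z_stack", "time_lapse"))
    if (is.null(x[[f]]))
      .stopInvalid("settings validation: missing field '%s'", f)
  ch <- x$channels
  if (length(ch) < 1L)
    .stopInvalid("settings validation: 'channels' must not be empty")
  nm <- vapply(ch, function(c.) {
    if (is.null(c.$name) || is.null(c.$exposure))
      .stopInvalid("settings validation: channel entries need 'name' and 'exposure'")
    c.$name
  }, character(1))
  ex <- vapply(ch, function(c.) as.numeric(c.$exposure), numeric(1))
  for (f in c("n_slices", "step_um"))
    if (is.null(x$z_stack[[f]]))
      .stopInvalid("settings validation: missing field 'z_stack.%s'", f)
  for (f in c("n_frames", "interval_s"))
    if (is.null(x$time_lapse[[f]]))
      .stopInvalid("settings validation: missing field 'time_lapse.%s'", f)
  acquisitionSettings(x$id, .objectiveFromList(x$objective), x$zoom,
                      x$image_width, x$image_height,
                      data.frame(name = nm, exposure = ex),
                      c(n_slices = as.numeric(x$z_stack$n_slices),
                        step_um = as.numeric(x$z_stack$step_um)),
                      c(n_frames = as.numeric(x$time_lapse$n_frames),
                        interval_s = as.numeric(x$time_lapse$interval_s)))
}

#' Read / write acquisition-settings files
#'
#' The settings dialect is a versioned JSON document with canonical output
#' (sorted keys, 9-significant-digit numbers, LF line ending), so writing
#' is deterministic and read/write round-trips are byte-identical after
#' canonicalization. Schema violations raise an error naming the
#' offending field; an unknown `schema_version` raises a version error.
#'
#' @param source,sink file paths.
#' @param settings an [AcquisitionSettings-class].
#' @return `readSettings` the settings object; `writeSettings` the path,
#'   invisibly.
#' @examples
#' obj <- objectiveProfile("10x", 10, 1500, 1500)
#' s <- acquisitionSettings("first", obj, imageWidth = 256,
#'                          imageHeight = 256, channels = c(dapi = 1))
#' p <- tempfile(fileext = ".json")
#' writeSettings(s, p)
#' identical(.Last.value, p)
#' readSettings(p)@id
#' @export
readSettings <- function(source) {
  .settingsFromList(.readJSON(source))
}

#' @rdname readSettings
#' @export
writeSettings <- function(settings, sink) {
  stopifnot(is(settings, "AcquisitionSettings"))
  validObject(settings)
  .writeCanonicalJSON(.settingsToList(settings), sink)
}

setMethod("show", "AcquisitionSettings", function(object) {
  fov <- effectiveFov(object)
  cat(sprintf(
    "AcquisitionSettings '%s': %s, zoom %g, %d x %d px (FOV %g x %g um)\n",
    object@id, object@objective@name, object@zoom, object@imageWidth,
    object@imageHeight, fov[["w"]], fov[["h"]]))
  cat(sprintf("  channels: %s; z %g x %g um; t %g x %g s\n",
    paste(object@channels$name, collapse = ", "),
    object@zStack[["n_slices"]], object@zStack[["step_um"]],
    object@timeLapse[["n_frames"]], object@timeLapse[["interval_s"]]))
})
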