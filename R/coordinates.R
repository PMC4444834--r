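# Coordinate lists: the macro-contract CSV. Fixed header, micrometre
# units, period decimal separator, UTF-8, LF line endings - a bit-exact
# contract so any external analysis routine can participate.

.COORD_HEADER <- c("object_id", "x_um", "y_um", "bbox_w_um", "bbox_h_um",
                   "label", "score")

#' Empty coordinate table
#'
#' @return a zero-row data.frame with the canonical coordinate columns.
#' @export
emptyCoordinates <- function() {
  data.frame(object_id = character(), x_um = numeric(), y_um = numeric(),
             bbox_w_um = numeric(), bbox_h_um = numeric(),
             label = character(), score = numeric())
}

.checkCoordinates <- function(records) {
  if (!is.data.frame(records) || !all(.COORD_HEADER %in% names(records)))
    .stopInvalid("coordinate records must have columns %s",
                 paste(.COORD_HEADER, collapse = ", "))
  if (any(records$bbox_w_um < 0) || any(records$bbox_h_um < 0))
    .stopInvalid("bbox dimensions must be >= 0")
  bad <- grepl(",", paste(records$object_id, records$label))
  if (any(bad))
    .stopInvalid("object ids and labels must not contain commas")
  records[.COORD_HEADER]
}

#' Read / write coordinate CSV files
#'
#' The list-of-coordinates contract between image analysis and the
#' second scan. Header: `object_id,x_um,y_um,bbox_w_um,bbox_h_um,label,score`.
#' `x_um`/`y_um` are the object centroid on the stage; the bounding box is
#' centred on it. Row order is preserved; writing is canonical (9
#' significant digits, LF endings) so identical records produce
#' byte-identical files. Malformed rows raise an error citing the line
#' number.
#'
#' @param source,sink file paths.
#' @param records a data.frame as returned by [emptyCoordinates()].
#' @return `readCoordinates` the records data.frame; `writeCoordinates`
#'   the path, invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' r <- data.frame(object_id = "obj1", x_um = 10.5, y_um = -3,
#'                 bbox_w_um = 20, bbox_h_um = 15, label = "tissue",
#'                 score = 1)
#' writeCoordinates(r, p)
#' readCoordinates(p)
#' @export
readCoordinates <- function(source) {
  lines <- readLines(source, encoding = "UTF-8")
  if (length(lines) == 0L)
    .stopInvalid("coordinate file '%s' is empty (header required)", source)
  if (!identical(lines[1], paste(.COORD_HEADER, collapse = ",")))
    .stopInvalid("coordinate file '%s': bad header at line 1", source)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(emptyCoordinates())
  parts <- strsplit(body, ",", fixed = TRUE)
  numCols <- c(2L, 3L, 4L, 5L, 7L)
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    p <- parts[[i]]
    if (length(p) != 7L)
      .stopInvalid("coordinate file '%s': expected 7 fields at line %d",
                   source, i + 1L)
    v <- suppressWarnings(as.numeric(p[numCols]))
    if (anyNA(v))
      .stopInvalid("coordinate file '%s': parse error at line %d (non-numeric value '%s')",
                   source, i + 1L, p[numCols][which(is.na(v))[1]])
    recs[[i]] <- data.frame(object_id = p[1], x_um = v[1], y_um = v[2],
                            bbox_w_um = v[3], bbox_h_um = v[4], label = p[6],
                            score = v[5])
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  .checkCoordinates(out)
}

#' @rdname readCoordinates
#' @export
writeCoordinates <- function(records, sink) {
  records <- .checkCoordinates(records)
  lines <- paste(.COORD_HEADER, collapse = ",")
  if (nrow(records) > 0L) {
    lines <- c(lines, vapply(seq_len(nrow(records)), function(i)
      paste(records$object_id[i], .fmtNum(records$x_um[i]),
            .fmtNum(records$y_um[i]), .fmtNum(records$bbox_w_um[i]),
            .fmtNum(records$bbox_h_um[i]), records$label[i],
            .fmtNum(records$score[i]), sep = ","), character(1)))
  }
  con <- file(sink, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(sink)
}
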