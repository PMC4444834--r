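# Canonical serialization and seeding helpers shared across modules.

# Canonical number formatting: shortest of up-to-9-significant-digit
# decimal representations; integers print without exponent or trailing
# zeros so identical values always yield identical bytes.
.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) stop("cannot serialize NA numbers")
    s <- sprintf("%.9g", v)
    # normalize "-0" to "0"
    if (s == "-0") s <- "0"
    s
  }, character(1))
}

.jsonEscape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  s <- gsub("\r", "\\\\r", s)
  s <- gsub("\t", "\\\\t", s)
  s
}

# Canonical JSON: sorted object keys, fixed number formatting, no
# whitespace variation. `null` is emitted for NULL leaves (used for
# unbounded values such as maxArea = Inf).
.toCanonicalJSON <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nm != "")) {
      o <- order(nm, method = "radix")
      parts <- vapply(o, function(i)
        paste0("\"", .jsonEscape(nm[i]), "\":", .toCanonicalJSON(x[[i]])),
        character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(x, .toCanonicalJSON, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (length(x) != 1L) {
    # unnamed vector -> array
    return(paste0("[", paste(vapply(seq_along(x),
      function(i) .toCanonicalJSON(x[[i]]), character(1)), collapse = ","),
      "]"))
  }
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) {
    if (!is.finite(x)) stop("cannot serialize non-finite number; use NULL")
    return(.fmtNum(x))
  }
  if (is.character(x)) return(paste0("\"", .jsonEscape(x), "\""))
  stop("unsupported type in canonical JSON: ", class(x)[1])
}

.writeCanonicalJSON <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(.toCanonicalJSON(x), "\n")), con)
  invisible(path)
}

.readJSON <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Deterministic 31-bit string hash (polynomial rolling hash); used to give
# every acquisition item its own reproducible noise stream.
.hashString <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

.deriveSeed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
              .hashString(as.character(id))) %% 2147483647)
}

# Evaluate expr under a temporary RNG state so library code never
# perturbs the caller's random stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopInvalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Axis-aligned stage rectangle
#'
#' Convenience constructor for the `c(x, y, w, h)` rectangle convention
#' (min corner + size, micrometres) used for sample bounds, bounding
#' boxes and layout slots.
#'
#' @param x,y min corner, micrometres.
#' @param w,h size, micrometres (> 0 for bounds; >= 0 for boxes).
#' @return named numeric of length 4.
#' @examples
#' rectUm(0, 0, 1000, 500)
#' @export
rectUm <- function(x, y, w, h) {
  stopifnot(is.finite(x), is.finite(y), is.finite(w), is.finite(h), w >= 0,
            h >= 0)
  c(x = x, y = y, w = w, h = h)
}

.asRect <- function(b) {
  if (!is.numeric(b) || length(b) != 4L)
    .stopInvalid("bounds must be numeric c(x, y, w, h)")
  if (is.null(names(b)) || !all(c("x", "y", "w", "h") %in% names(b)))
    names(b) <- c("x", "y", "w", "h")
  b[c("x", "y", "w", "h")]
}
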