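# Annotated intracardiac electrogram event series: the interchange object for
# every other module. An event series is a tibble of fiducial annotations
# (no waveforms) plus a free-form metadata list carried as an attribute.

#' Recording channels and event kinds
#'
#' The fixed catheter set of a standard SVT study: right ventricular apex
#' (RVA), His bundle (HIS), high right atrium (HRA) and three coronary-sinus
#' poles (proximal/mid/distal). Channel order doubles as the tie-break
#' priority when events are simultaneous.
#'
#' @format Character vectors.
#' @name egm_enums
NULL

#' @rdname egm_enums
#' @export
EGM_CHANNELS <- c("RVA", "HIS", "HRA", "CS_PROX", "CS_MID", "CS_DIST")

#' @rdname egm_enums
#' @export
EGM_KINDS <- c("STIM", "V", "H", "A")

#' @rdname egm_enums
#' @export
EGM_ORIGINS <- c("PACED", "CONDUCTED", "UNKNOWN")

# Minimum separation between two annotations of the same kind on one channel.
# This is an annotation-hygiene rule (physiologic refractory floor), not a
# measurement parameter.
EGM_SAME_KIND_FLOOR_MS <- 30

# Absolute tolerance for interval comparisons throughout the package.
MS_TOL <- 0.05

match_enum <- function(x, levels, what, arg = what) {
  x <- toupper(trimws(as.character(x)))
  bad <- !(x %in% levels) & !is.na(x)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s value(s): %s (expected one of %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Construct an electrogram event series
#'
#' Builds a validated, time-sorted event series from a data frame of
#' annotations. Simultaneous events are ordered by channel priority
#' (RVA < HIS < HRA < CS_PROX < CS_MID < CS_DIST) and then by kind
#' (STIM < V < H < A), so sorting is deterministic.
#'
#' @param events A data frame with columns `time_ms` (non-negative,
#'   milliseconds from recording start), `channel`, `kind` and optionally
#'   `origin` (defaults to `"UNKNOWN"`; `STIM` events are always `PACED`).
#'   Enumerations are parsed case-insensitively.
#' @param meta Named list of protocol metadata (pacing mode, cycle lengths,
#'   mechanism label, seed, ...). Values are coerced to scalars on file
#'   round-trip.
#' @return A tibble of class `egm_series` with a `meta` attribute.
#' @examples
#' s <- egm_series(data.frame(
#'   time_ms = c(0, 140, 400), channel = c("RVA", "HRA", "RVA"),
#'   kind = c("STIM", "A", "V")
#' ))
#' s
#' @export
egm_series <- function(events, meta = list()) {
  events <- tibble::as_tibble(events)
  required <- c("time_ms", "channel", "kind")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("origin" %in% names(events))) events$origin <- "UNKNOWN"

  events$time_ms <- as.numeric(events$time_ms)
  events$channel <- match_enum(events$channel, EGM_CHANNELS, "channel")
  events$kind <- match_enum(events$kind, EGM_KINDS, "kind")
  events$origin <- match_enum(events$origin, EGM_ORIGINS, "origin")
  events$origin[events$kind == "STIM"] <- "PACED"

  if (any(!is.finite(events$time_ms)) || any(events$time_ms < 0)) {
    bad <- which(!is.finite(events$time_ms) | events$time_ms < 0)[1]
    stop(sprintf("event %d has non-finite or negative time_ms", bad),
         call. = FALSE)
  }
  bad_h <- events$kind == "H" & events$channel != "HIS"
  if (any(bad_h)) {
    stop(sprintf("H events are only valid on channel HIS (event at t=%.1f on %s)",
                 events$time_ms[which(bad_h)[1]],
                 events$channel[which(bad_h)[1]]), call. = FALSE)
  }

  ord <- order(events$time_ms,
               match(events$channel, EGM_CHANNELS),
               match(events$kind, EGM_KINDS))
  events <- events[ord, , drop = FALSE]

  validate_refractory_floor(events)

  structure(events,
            class = c("egm_series", class(tibble::tibble())),
            meta = meta)
}

validate_refractory_floor <- function(events) {
  if (nrow(events) < 2) return(invisible(TRUE))
  key <- paste(events$channel, events$kind)
  for (k in unique(key)) {
    t <- events$time_ms[key == k]
    if (length(t) < 2) next
    dt <- diff(t)
    if (any(dt < EGM_SAME_KIND_FLOOR_MS - MS_TOL)) {
      i <- which(dt < EGM_SAME_KIND_FLOOR_MS - MS_TOL)[1]
      stop(sprintf(
        "events closer than %d ms on the same channel/kind (%s at t=%.1f and t=%.1f)",
        EGM_SAME_KIND_FLOOR_MS, k, t[i], t[i + 1]
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.egm_series <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<egm_series: %d events", nrow(x)))
  if (nrow(x) > 0) cat(sprintf(", %.1f-%.1f ms", min(x$time_ms), max(x$time_ms)))
  cat(">\n")
  if (length(meta) > 0) {
    cat("meta:", paste(names(meta), unlist(lapply(meta, format)),
                       sep = "=", collapse = "  "), "\n")
  }
  NextMethod()
}

#' Access or set event-series metadata
#'
#' @param series An `egm_series`.
#' @return `egm_meta()` returns the metadata list.
#' @export
egm_meta <- function(series) {
  attr(series, "meta") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_egm_meta <- function(series, meta) {
  attr(series, "meta") <- meta
  series
}

#' Read an annotated event table
#'
#' The interchange format is UTF-8 comma-delimited text: optional metadata
#' lines `#key=value` first, then a header `time_ms,channel,kind,origin`,
#' then one row per event. Enumerations are parsed case-insensitively and the
#' returned series is validated and sorted.
#'
#' @param path Path to the file.
#' @return A validated `egm_series`.
#' @export
read_event_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^#", lines[i])) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop(sprintf("line %d: malformed metadata line '%s'", i, lines[i]),
                     call. = FALSE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    i <- i + 1L
  }
  if (i > length(lines)) stop("file has no header line", call. = FALSE)
  header <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
  if (!identical(tolower(trimws(header)), c("time_ms", "channel", "kind", "origin"))) {
    stop(sprintf("line %d: expected header 'time_ms,channel,kind,origin'", i),
         call. = FALSE)
  }
  body <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  body_line_no <- seq.int(i + 1L, length.out = length(body))
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_line_no <- body_line_no[keep]

  if (length(body) == 0) {
    return(egm_series(tibble::tibble(time_ms = numeric(), channel = character(),
                                     kind = character(), origin = character()),
                      meta = meta))
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    j <- which(nf != 4L)[1]
    stop(sprintf("line %d: expected 4 fields, found %d", body_line_no[j], nf[j]),
         call. = FALSE)
  }
  m <- matrix(trimws(unlist(fields)), ncol = 4, byrow = TRUE)
  t_ms <- suppressWarnings(as.numeric(m[, 1]))
  if (any(is.na(t_ms))) {
    j <- which(is.na(t_ms))[1]
    stop(sprintf("line %d: non-numeric time_ms '%s'", body_line_no[j], m[j, 1]),
         call. = FALSE)
  }
  egm_series(tibble::tibble(time_ms = t_ms, channel = m[, 2],
                            kind = m[, 3], origin = m[, 4]),
             meta = meta)
}

#' Write an annotated event table
#'
#' Times are serialized with 0.1 ms precision; `read_event_table()` of the
#' output reproduces the series (round-trip identity on series whose times
#' lie on the 0.1 ms grid, as all simulator output does).
#'
#' @param series An `egm_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_event_table <- function(series, path) {
  stopifnot(inherits(series, "egm_series"))
  meta <- egm_meta(series)
  meta_lines <- if (length(meta) > 0) {
    vapply(names(meta), function(k) sprintf("#%s=%s", k, format(meta[[k]], trim = TRUE)),
           character(1))
  } else character(0)
  rows <- if (nrow(series) > 0) {
    sprintf("%.1f,%s,%s,%s", series$time_ms, series$channel, series$kind,
            series$origin)
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta_lines, "time_ms,channel,kind,origin", rows), con = con,
             useBytes = TRUE)
  invisible(path)
}

#' Extract a half-open time window from an event series
#'
#' Returns the events with `t0 <= time_ms < t1`; metadata is preserved.
#'
#' @param series An `egm_series`.
#' @param t0,t1 Window bounds in ms, `t0 <= t1`. `t1` may be `Inf`.
#' @return An `egm_series`.
#' @export
window_events <- function(series, t0, t1) {
  stopifnot(inherits(series, "egm_series"))
  if (t0 > t1) stop("t0 must be <= t1", call. = FALSE)
  keep <- series$time_ms >= t0 & series$time_ms < t1
  out <- series[keep, , drop = FALSE]
  set_egm_meta(out, egm_meta(series))
}
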