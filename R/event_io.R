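# Reading, writing and validating sensor event logs and home layouts.
#
# Canonical event CSV: columns timestamp,sensor_id,state with ISO-8601 local
# timestamps at second resolution. Only rows whose state indicates a motion
# detection become events; clear/off rows are dropped (PIR firings are treated
# as point events).

MOTION_STATES <- c("on", "1", "true", "detected", "motion", "active")
CLEAR_STATES <- c("off", "0", "false", "clear", "inactive", "none")

#' Construct a home layout
#'
#' A layout maps opaque sensor ids to room labels for one single-occupant
#' home. At most one sensor per room label except `"other"`; exactly one
#' bedroom (the sleeping room); at least one PIR sensor. An optional
#' `entrance_door` sensor marks the home boundary and never receives
#' occupancy.
#'
#' @param home_id opaque home identifier.
#' @param sensors named character vector `sensor_id -> room label` (labels
#'   from [room_labels()] with the door included).
#' @param timezone IANA timezone name governing local day boundaries.
#' @return an object of class `home_layout`.
#' @export
home_layout <- function(home_id, sensors, timezone = "UTC") {
  stopifnot(is.character(home_id), length(home_id) == 1L)
  if (is.null(names(sensors)) || any(!nzchar(names(sensors))))
    stop("layout error: 'sensors' must be a named character vector (sensor_id -> room)")
  bad <- setdiff(unique(sensors), SENSOR_LABELS)
  if (length(bad))
    stop("layout error: unknown room label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(sensors)))
    stop("layout error: duplicated sensor_id")
  pir <- sensors[sensors != "entrance_door"]
  if (length(pir) < 1L) stop("layout error: at least one PIR sensor required")
  tab <- table(pir[pir != "other"])
  if (any(tab > 1L))
    stop("layout error: more than one sensor for room(s): ",
         paste(names(tab)[tab > 1L], collapse = ", "))
  if (sum(pir == "bedroom") != 1L)
    stop("layout error: exactly one bedroom sensor required")
  if (!timezone %in% OlsonNames())
    stop("layout error: unknown timezone: ", timezone)
  structure(
    list(home_id = home_id, sensors = sensors, timezone = timezone),
    class = "home_layout"
  )
}

#' @export
print.home_layout <- function(x, ...) {
  cat("Home layout", x$home_id, "(", x$timezone, ")\n")
  for (i in seq_along(x$sensors))
    cat(sprintf("  %-12s -> %s\n", names(x$sensors)[i], x$sensors[[i]]))
  invisible(x)
}

#' Read / write a home layout (JSON)
#'
#' Layout JSON schema: `{"home_id": ..., "timezone": ...,
#' "sensors": [{"id": ..., "room": ...}, ...]}`.
#'
#' @param path file path.
#' @return [read_home_layout()] returns a `home_layout`.
#' @export
read_home_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$home_id) || is.null(j$sensors))
    stop("layout error: JSON must contain home_id and sensors")
  sensors <- stats::setNames(as.character(j$sensors$room), j$sensors$id)
  home_layout(as.character(j$home_id), sensors,
              timezone = if (is.null(j$timezone)) "UTC" else j$timezone)
}

#' @rdname read_home_layout
#' @param layout a `home_layout`.
#' @export
write_home_layout <- function(layout, path) {
  jsonlite::write_json(
    list(home_id = layout$home_id, timezone = layout$timezone,
         sensors = data.frame(id = names(layout$sensors),
                              room = unname(layout$sensors))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct an event log
#'
#' @param timestamp `POSIXct` firing times (second resolution).
#' @param sensor_id character sensor ids.
#' @param room character room labels resolved through the layout.
#' @param home_id home identifier.
#' @param timezone IANA zone used for local day/hour arithmetic.
#' @return an `event_log`: a data frame with columns `timestamp`, `sensor_id`,
#'   `room`, plus attributes `home_id`, `timezone` and `span_days` (number of
#'   distinct local calendar days touched by events).
#' @export
event_log <- function(timestamp, sensor_id, room, home_id, timezone = "UTC") {
  stopifnot(inherits(timestamp, "POSIXct") || length(timestamp) == 0L)
  ord <- order(timestamp, sensor_id)
  df <- data.frame(
    timestamp = as.POSIXct(timestamp, tz = timezone)[ord],
    sensor_id = as.character(sensor_id)[ord],
    room = as.character(room)[ord],
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(df$room), SENSOR_LABELS)
  if (length(bad)) stop("event_log: unknown room label(s): ",
                        paste(bad, collapse = ", "))
  span <- if (nrow(df)) length(unique(format(df$timestamp, "%Y-%m-%d",
                                             tz = timezone))) else 0L
  structure(df, home_id = home_id, timezone = timezone, span_days = span,
            class = c("event_log", "data.frame"))
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log %s: %d firings over %d day(s) [%s]\n",
              attr(x, "home_id"), nrow(x), attr(x, "span_days"),
              attr(x, "timezone")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

log_tz <- function(log) attr(log, "timezone") %||% "UTC"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sensor event log from canonical CSV
#'
#' Reads `timestamp,sensor_id,state` rows, keeps motion-detected states,
#' resolves rooms through the layout, collapses duplicate
#' `(sensor, timestamp)` rows and sorts by time.
#'
#' @param path CSV path.
#' @param layout a [home_layout()] resolving every `sensor_id` in the file.
#' @return an [event_log()].
#' @export
read_event_log <- function(path, layout) {
  stopifnot(inherits(layout, "home_layout"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("timestamp", "sensor_id", "state")
  if (!all(need %in% names(df)))
    stop("parse error: expected columns ", paste(need, collapse = ","))
  if (nrow(df) == 0L)
    return(event_log(as.POSIXct(character(), tz = layout$timezone),
                     character(), character(), layout$home_id,
                     layout$timezone))
  keep <- tolower(df$state) %in% MOTION_STATES
  if (any(!keep & !(tolower(df$state) %in% CLEAR_STATES)))
    warning("dropping rows with unrecognized state values")
  df <- df[keep, , drop = FALSE]
  unknown <- setdiff(unique(df$sensor_id), names(layout$sensors))
  if (length(unknown))
    stop("layout error: unknown sensor_id(s): ", paste(unknown, collapse = ", "))
  ts <- parse_iso_local(df$timestamp, layout$timezone)
  if (anyNA(ts)) {
    line <- which(is.na(ts))[1L] + 1L  # +1 for header
    stop(sprintf("parse error: malformed timestamp at line %d: '%s'",
                 line, df$timestamp[which(is.na(ts))[1L]]))
  }
  dup <- duplicated(data.frame(df$sensor_id, as.numeric(ts)))
  df <- df[!dup, , drop = FALSE]
  ts <- ts[!dup]
  event_log(ts, df$sensor_id, unname(layout$sensors[df$sensor_id]),
            layout$home_id, layout$timezone)
}

parse_iso_local <- function(x, tz) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  # permit date-only / minute-resolution rows
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = tz, format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Write a sensor event log as canonical CSV
#'
#' @param log an [event_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  df <- data.frame(
    timestamp = format(log$timestamp, "%Y-%m-%dT%H:%M:%S", tz = log_tz(log)),
    sensor_id = log$sensor_id,
    state = "on"
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adapt a foreign event table to the canonical schema
#'
#' Pluggable reader for externally deposited datasets whose exact column
#' naming is unknown ahead of time. Columns are matched case-insensitively
#' against synonym lists; explicit `*_col` arguments override guessing.
#' Ambiguous or missing matches fail loudly rather than guessing silently.
#'
#' @param df a data frame with at least a timestamp column and a sensor (or
#'   room) column.
#' @param timestamp_col,sensor_col,state_col optional explicit column names.
#' @return a data frame in canonical `timestamp,sensor_id,state` form, ready
#'   to be written with [utils::write.csv()] and read by [read_event_log()].
#' @export
adapt_event_table <- function(df, timestamp_col = NULL, sensor_col = NULL,
                              state_col = NULL) {
  pick <- function(explicit, synonyms, what, required = TRUE) {
    if (!is.null(explicit)) {
      if (!explicit %in% names(df))
        stop("adapter error: column '", explicit, "' not present")
      return(explicit)
    }
    hits <- names(df)[tolower(names(df)) %in% synonyms]
    if (length(hits) > 1L)
      stop("adapter error: ambiguous ", what, " columns: ",
           paste(hits, collapse = ", "))
    if (length(hits) == 0L) {
      if (required) stop("adapter error: no ", what, " column found among: ",
                         paste(names(df), collapse = ", "))
      return(NULL)
    }
    hits
  }
  tcol <- pick(timestamp_col,
               c("timestamp", "time", "datetime", "date_time", "last_changed",
                 "fecha", "when"), "timestamp")
  scol <- pick(sensor_col,
               c("sensor_id", "sensor", "entity_id", "device", "room",
                 "location", "habitacion"), "sensor")
  vcol <- pick(state_col, c("state", "status", "value", "estado"),
               "state", required = FALSE)
  out <- data.frame(
    timestamp = as.character(df[[tcol]]),
    sensor_id = as.character(df[[scol]]),
    state = if (is.null(vcol)) "on" else as.character(df[[vcol]]),
    stringsAsFactors = FALSE
  )
  out
}
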