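# Presence inference: turn point PIR firings into room-occupancy intervals.
#
# The rule: a firing in room R attests presence in R for at least the sensor
# hold time. A silent gap bounded by two firings in the SAME room, with no
# other PIR or entrance-door firing in between, is attributed to continued
# occupancy of that room (gap filling). A gap bounded by different rooms, or
# interrupted by the entrance door, is left unattributed ("unknown") from the
# end of the hold window to the next firing. Door firings never create
# occupancy.

#' Construct an occupancy timeline
#'
#' @param intervals data frame with columns `room`, `start`, `end`
#'   (`POSIXct`), `basis` (`"observed"` or `"gap_filled"`).
#' @param home_id home identifier.
#' @param unknown_time total unattributed duration, seconds.
#' @param span_start,span_end `POSIXct` bounds of the covered span.
#' @param timezone IANA zone for local day arithmetic.
#' @return object of class `occupancy_timeline` (a data frame with metadata
#'   attributes).
#' @export
occupancy_timeline <- function(intervals, home_id, unknown_time,
                               span_start, span_end, timezone = "UTC") {
  if (nrow(intervals)) {
    stopifnot(all(intervals$end > intervals$start),
              all(intervals$room %in% ROOM_LABELS),
              all(intervals$basis %in% c("observed", "gap_filled")))
    if (any(diff(as.numeric(intervals$start)) < 0))
      stop("occupancy_timeline: intervals must be time-ordered")
    if (nrow(intervals) > 1L &&
        any(as.numeric(intervals$start[-1L]) <
            as.numeric(intervals$end[-nrow(intervals)]) - 1e-9))
      stop("occupancy_timeline: intervals overlap")
  }
  structure(intervals, home_id = home_id, unknown_time = unknown_time,
            span_start = span_start, span_end = span_end, timezone = timezone,
            class = c("occupancy_timeline", "data.frame"))
}

#' @export
print.occupancy_timeline <- function(x, ...) {
  span <- as.numeric(attr(x, "span_end")) - as.numeric(attr(x, "span_start"))
  cat(sprintf("Occupancy timeline %s: %d intervals, span %.1f h, unknown %.1f h (%.1f%%)\n",
              attr(x, "home_id"), nrow(x), span / 3600,
              attr(x, "unknown_time") / 3600,
              if (span > 0) 100 * attr(x, "unknown_time") / span else 0))
  invisible(x)
}

#' Infer room presence from a PIR event log
#'
#' @param log an [event_log()], time-sorted.
#' @param hold sensor hold (retrigger) time in seconds: the minimum presence
#'   attested by a single firing. Default 60 s.
#' @param max_fill_gap longest silent same-room gap that is filled as
#'   continued occupancy, seconds; `Inf` (default) fills unconditionally.
#' @return an [occupancy_timeline()]. Its `unknown_time` attribute holds the
#'   total unattributed duration; attributed durations plus `unknown_time`
#'   tile the span from the first firing to the last firing + `hold` exactly.
#' @export
infer_presence <- function(log, hold = 60, max_fill_gap = Inf) {
  stopifnot(hold > 0, max_fill_gap > 0)
  tz <- log_tz(log)
  empty <- occupancy_timeline(
    data.frame(room = character(), start = as.POSIXct(character(), tz = tz),
               end = as.POSIXct(character(), tz = tz), basis = character()),
    attr(log, "home_id"), 0,
    as.POSIXct(NA), as.POSIXct(NA), tz)
  n <- nrow(log)
  if (n == 0L) return(empty)
  t <- as.numeric(log$timestamp)
  if (is.unsorted(t)) stop("infer_presence: log must be sorted by timestamp")
  r <- log$room
  door <- r == "entrance_door"
  if (n > 1L) {
    dt <- diff(t)
    brk <- r[-1L] != r[-n] | door[-1L] | door[-n] | dt > max_fill_gap
    grp <- cumsum(c(0L, brk))
  } else grp <- 0L
  first_i <- which(!duplicated(grp))
  last_i <- c(first_i[-1L] - 1L, n)
  keep <- !door[first_i]
  start <- t[first_i]
  # next event of any kind truncates the hold window of the last firing
  nxt <- c(t[-1L], Inf)[last_i]
  end <- pmin(t[last_i] + hold, nxt)
  filled <- vapply(seq_along(first_i), function(g) {
    i0 <- first_i[g]; i1 <- last_i[g]
    i1 > i0 && any(diff(t[i0:i1]) > hold)
  }, logical(1))
  ok <- keep & end > start
  iv <- data.frame(
    room = r[first_i][ok],
    start = as.POSIXct(start[ok], tz = tz, origin = "1970-01-01"),
    end = as.POSIXct(end[ok], tz = tz, origin = "1970-01-01"),
    basis = ifelse(filled[ok], "gap_filled", "observed"),
    stringsAsFactors = FALSE
  )
  span_start <- t[1L]
  span_end <- t[n] + hold
  unknown <- (span_end - span_start) - sum(end[ok] - start[ok])
  occupancy_timeline(iv, attr(log, "home_id"), unknown,
                     as.POSIXct(span_start, tz = tz, origin = "1970-01-01"),
                     as.POSIXct(span_end, tz = tz, origin = "1970-01-01"), tz)
}

#' Split timeline intervals at local midnight
#'
#' Day-spanning intervals are cut at each local midnight; both halves keep
#' their basis. Useful for per-day export and per-day occupancy statistics.
#'
#' @param timeline an [occupancy_timeline()].
#' @return an [occupancy_timeline()] with no interval crossing midnight.
#' @export
split_at_midnight <- function(timeline) {
  if (nrow(timeline) == 0L) return(timeline)
  tz <- attr(timeline, "timezone")
  pieces <- lapply(seq_len(nrow(timeline)), function(i) {
    s <- timeline$start[i]; e <- timeline$end[i]
    cuts <- seq(from = as.POSIXct(format(s, "%Y-%m-%d", tz = tz), tz = tz),
                to = e, by = "1 day")
    cuts <- cuts[cuts > s & cuts < e]
    bounds <- c(s, cuts, e)
    data.frame(room = timeline$room[i],
               start = bounds[-length(bounds)], end = bounds[-1L],
               basis = timeline$basis[i], stringsAsFactors = FALSE)
  })
  occupancy_timeline(do.call(rbind, pieces), attr(timeline, "home_id"),
                     attr(timeline, "unknown_time"),
                     attr(timeline, "span_start"), attr(timeline, "span_end"),
                     tz)
}

#' Write an occupancy timeline as CSV
#'
#' Columns `home_id,room,start,end,basis`; intervals split at local midnight
#' so each row belongs to one calendar day.
#'
#' @param timeline an [occupancy_timeline()].
#' @param path output path.
#' @param split split at midnight before writing (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path, split = TRUE) {
  if (split) timeline <- split_at_midnight(timeline)
  tz <- attr(timeline, "timezone")
  df <- data.frame(
    home_id = attr(timeline, "home_id"),
    room = timeline$room,
    start = format(timeline$start, "%Y-%m-%dT%H:%M:%S", tz = tz),
    end = format(timeline$end, "%Y-%m-%dT%H:%M:%S", tz = tz),
    basis = timeline$basis
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
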