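# Hourly activity profiles and room-occupancy statistics.
#
# "Activity level" is operationalized as the PIR firing count per hour of the
# day, averaged over monitored days — the only quantity the raw point events
# support directly. Entrance-door firings are excluded throughout: they mark
# the home boundary, not in-home activity.

#' Hourly activity profile of one participant
#'
#' Bin `b` (0-23) holds the mean number of PIR firings with local hour `b`
#' per monitored day. By default the denominator is the number of calendar
#' days with at least one PIR firing, so outage days do not dilute the mean.
#'
#' @param log an [event_log()], non-empty.
#' @param n_days optional explicit denominator (e.g. the nominal number of
#'   monitored days); default `NULL` counts days with >= 1 firing.
#' @return a `daily_profile`: numeric vector of length 24 with attributes
#'   `home_id` and `n_days`.
#' @export
hourly_activity_profile <- function(log, n_days = NULL) {
  tz <- log_tz(log)
  ev <- log[log$room != "entrance_door", , drop = FALSE]
  if (nrow(ev) == 0L) stop("hourly_activity_profile: no PIR firings in log")
  hour <- as.integer(format(ev$timestamp, "%H", tz = tz))
  day <- format(ev$timestamp, "%Y-%m-%d", tz = tz)
  if (is.null(n_days)) n_days <- length(unique(day))
  stopifnot(n_days >= 1)
  counts <- tabulate(hour + 1L, nbins = 24L)
  structure(counts / n_days,
            names = sprintf("h%02d", 0:23),
            home_id = attr(log, "home_id"), n_days = n_days,
            class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf("Daily activity profile %s (%d day(s)); peak hour %d (%.2f firings/h)\n",
              attr(x, "home_id") %||% "?", attr(x, "n_days"),
              which.max(unclass(x)) - 1L, max(x)))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Stack profiles into a participant-by-hour matrix
#'
#' @param profiles list of [hourly_activity_profile()] results (or bare
#'   24-vectors).
#' @return numeric matrix, one row per participant, 24 columns.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  m <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(length(p) == 24L)
    as.numeric(p)
  }))
  ids <- vapply(seq_along(profiles), function(i)
    attr(profiles[[i]], "home_id") %||% names(profiles)[i] %||%
      sprintf("p%02d", i), character(1))
  dimnames(m) <- list(ids, sprintf("h%02d", 0:23))
  m
}

#' Population activity curve
#'
#' Bin-wise mean and first/third quartiles of hourly activity across
#' participants, each participant weighted equally regardless of days
#' monitored. Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param profiles list of profiles or a [profile_matrix()].
#' @return a `population_curve`: list with `mean`, `q1`, `q3` (24 values
#'   each) and `n` participants.
#' @export
population_curve <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  structure(list(
    mean = colMeans(m),
    q1 = apply(m, 2, stats::quantile, probs = 0.25, names = FALSE),
    q3 = apply(m, 2, stats::quantile, probs = 0.75, names = FALSE),
    n = nrow(m)
  ), class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf("Population activity curve over %d participant(s); mean peak at hour %d\n",
              x$n, which.max(x$mean) - 1L))
  invisible(x)
}

#' @export
plot.population_curve <- function(x, ...) {
  graphics::matplot(0:23, cbind(x$q1, x$mean, x$q3), type = "l",
                    lty = c(2, 1, 2), col = c("orange", "black", "orange"),
                    lwd = c(1, 2, 1), xlab = "hour of day",
                    ylab = "activity (firings/h)", ...)
  invisible(x)
}

#' Fraction of time spent in each room
#'
#' Attributed duration per room divided by the covered span; unattributed
#' time goes to `unknown`. Fractions sum to 1.
#'
#' @param timeline an [occupancy_timeline()] with positive span.
#' @return named numeric vector over [room_labels()] plus `unknown`.
#' @export
room_occupancy_fractions <- function(timeline) {
  span <- as.numeric(attr(timeline, "span_end")) -
    as.numeric(attr(timeline, "span_start"))
  if (!isTRUE(span > 0)) stop("room_occupancy_fractions: timeline span is zero")
  dur <- as.numeric(timeline$end) - as.numeric(timeline$start)
  by_room <- vapply(ROOM_LABELS, function(r) sum(dur[timeline$room == r]),
                    numeric(1))
  frac <- by_room / span
  c(frac, unknown = max(0, 1 - sum(frac)))
}

#' Mean occupied minutes per room and hour of day
#'
#' Intervals are clipped at hour boundaries; entry `(room, h)` is the mean
#' number of minutes of hour `h` spent in `room`, over the monitored days.
#'
#' @param timeline an [occupancy_timeline()].
#' @param n_days optional denominator; default counts the distinct local
#'   calendar dates from span start to span end.
#' @return matrix `length(room_labels())` x 24, entries in `[0, 60]`.
#' @export
hourly_room_usage <- function(timeline, n_days = NULL) {
  tz <- attr(timeline, "timezone")
  if (is.null(n_days)) {
    d0 <- as.Date(format(attr(timeline, "span_start"), "%Y-%m-%d", tz = tz))
    d1 <- as.Date(format(attr(timeline, "span_end"), "%Y-%m-%d", tz = tz))
    n_days <- as.integer(d1 - d0) + 1L
  }
  stopifnot(n_days >= 1)
  acc <- matrix(0, nrow = length(ROOM_LABELS), ncol = 24L,
                dimnames = list(ROOM_LABELS, sprintf("h%02d", 0:23)))
  for (i in seq_len(nrow(timeline))) {
    s <- as.numeric(timeline$start[i]); e <- as.numeric(timeline$end[i])
    # local seconds-after-midnight of the interval start
    lt <- as.POSIXlt(timeline$start[i], tz = tz)
    off0 <- lt$hour * 3600 + lt$min * 60 + lt$sec
    cur <- 0
    while (cur < e - s) {
      pos <- (off0 + cur) %% 86400
      h <- floor(pos / 3600)
      nxt <- min(e - s, cur + (3600 - pos %% 3600))
      acc[timeline$room[i], h + 1L] <- acc[timeline$room[i], h + 1L] +
        (nxt - cur) / 60
      cur <- nxt
    }
  }
  acc / n_days
}
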