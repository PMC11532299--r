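# Rule-based wake-up and bedtime detection.
#
# Wake-up: the first firing of a PIR sensor outside the bedroom at or after
# the detection threshold (06:00 by default) on a given day. Bedroom firings
# never qualify — they may occur during sleep — and pre-threshold excursions
# (e.g. nycturia trips) are ignored entirely: the detector waits for the next
# qualifying post-threshold firing outside the bedroom.
#
# Bedtime: starting the search at 21:00, the first quiet window of at least
# one hour with no activity outside the bedroom; bedtime is the last
# non-bedroom firing preceding that window. Bedtimes after midnight are
# attributed to the previous evening's date.

local_midnight <- function(date, tz) {
  as.POSIXct(paste0(as.character(date), " 00:00:00"), tz = tz)
}

#' Detect wake-up time for one day
#'
#' @param log an [event_log()].
#' @param date local calendar date (`Date` or `"YYYY-MM-DD"`).
#' @param threshold earliest clock time at which a wake can be declared
#'   (`"HH:MM"` string or seconds after midnight; default `"06:00"`).
#' @return list with `home_id`, `date`, `wake_time` (`POSIXct` or `NA`),
#'   `wake_min` (minutes after midnight or `NA`) and `censored` (no
#'   qualifying firing that day).
#' @export
detect_wake_time <- function(log, date, threshold = "06:00") {
  tz <- log_tz(log)
  date <- as.Date(date)
  t <- as.numeric(log$timestamp)
  if (nrow(log) == 0L) stop("detect_wake_time: empty log")
  day0 <- as.numeric(local_midnight(date, tz))
  if (day0 + 86400 <= t[1L] || day0 >= t[nrow(log)] + 1)
    stop("detect_wake_time: date outside log span")
  thr <- day0 + parse_clock(threshold)
  ok <- t >= thr & t < day0 + 86400 &
    log$room != "bedroom" & log$room != "entrance_door"
  res <- list(home_id = attr(log, "home_id"), date = date,
              wake_time = as.POSIXct(NA), wake_min = NA_real_,
              censored = TRUE)
  if (any(ok)) {
    w <- min(t[ok])
    res$wake_time <- as.POSIXct(w, tz = tz, origin = "1970-01-01")
    res$wake_min <- (w - day0) / 60
    res$censored <- FALSE
  }
  res
}

#' Detect bedtime for one evening
#'
#' Scans from `search_start` on `date` up to `search_end` of the next
#' morning for the first window of `quiet` minutes with no activity outside
#' the bedroom (entrance-door firings also break the quiet). Bedtime is the
#' last non-bedroom PIR firing preceding that window and is attributed to
#' `date` even when it falls after midnight.
#'
#' @param log an [event_log()].
#' @param date local calendar date of the evening.
#' @param search_start clock time at which the search begins (default
#'   `"21:00"`).
#' @param search_end next-morning clock time at which the candidate search
#'   stops (default `"06:00"`), so morning lulls are never mistaken for
#'   bedtime.
#' @param quiet quiet-window length, minutes (default 60).
#' @return list with `home_id`, `date`, `bed_time` (`POSIXct` or `NA`),
#'   `bed_min` (minutes after midnight of `date`, may exceed 1440) and
#'   `censored`. A bedroom-only evening yields `bed_time = search_start`
#'   with `censored = TRUE`; insufficient log coverage yields `NA` with
#'   `censored = TRUE`.
#' @export
detect_bedtime <- function(log, date, search_start = "21:00",
                           search_end = "06:00", quiet = 60) {
  tz <- log_tz(log)
  date <- as.Date(date)
  day0 <- as.numeric(local_midnight(date, tz))
  start <- day0 + parse_clock(search_start)
  horizon <- day0 + 86400 + parse_clock(search_end)
  t <- as.numeric(log$timestamp)
  res <- list(home_id = attr(log, "home_id"), date = date,
              bed_time = as.POSIXct(NA), bed_min = NA_real_, censored = TRUE)
  if (nrow(log) == 0L) return(res)
  win <- t >= start & t <= horizon
  outside <- log$room != "bedroom"             # includes entrance_door
  cand <- win & outside & log$room != "entrance_door"
  if (!any(win & outside)) {
    # bedroom-only evening: already in bed when the search starts
    res$bed_time <- as.POSIXct(start, tz = tz, origin = "1970-01-01")
    res$bed_min <- (start - day0) / 60
    return(res)
  }
  breakers <- t[outside & t >= start]
  last_t <- t[nrow(log)]
  for (b in sort(t[cand])) {
    nxt <- breakers[breakers > b]
    gap_ok <- if (length(nxt)) nxt[1L] - b >= quiet * 60 else TRUE
    confirmed <- b + quiet * 60 <= last_t
    if (gap_ok && confirmed) {
      res$bed_time <- as.POSIXct(b, tz = tz, origin = "1970-01-01")
      res$bed_min <- (b - day0) / 60
      res$censored <- FALSE
      return(res)
    }
    if (gap_ok && !confirmed) return(res)  # log ends inside the quiet window
  }
  res
}

#' Detect wake-up (or bed-) times for every monitored day
#'
#' @param log an [event_log()].
#' @param dates local dates to scan; default all distinct dates in the log.
#' @param ... passed to [detect_wake_time()] / [detect_bedtime()].
#' @return data frame with one row per date: `home_id`, `date`, `time`
#'   (clock string or `NA`), `minutes` (after midnight of the attributed
#'   date) and `censored`.
#' @export
detect_wake_times <- function(log, dates = NULL, ...) {
  scan_days(log, dates, detect_wake_time, "wake_min", ...)
}

#' @rdname detect_wake_times
#' @export
detect_bedtimes <- function(log, dates = NULL, ...) {
  scan_days(log, dates, detect_bedtime, "bed_min", ...)
}

scan_days <- function(log, dates, fn, field, ...) {
  tz <- log_tz(log)
  if (is.null(dates))
    dates <- sort(unique(as.Date(format(log$timestamp, "%Y-%m-%d", tz = tz))))
  rows <- lapply(dates, function(d) {
    r <- fn(log, d, ...)
    data.frame(home_id = r$home_id, date = as.character(d),
               time = if (is.na(r[[field]])) NA_character_
                      else fmt_clock((r[[field]] %% 1440) * 60),
               minutes = r[[field]], censored = r$censored,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize detected wake (or bed) times
#'
#' Mean, standard deviation and quantiles of the uncensored times in minutes
#' after midnight, plus a weekday-versus-weekend location comparison
#' (Welch's two-sample t by default, Mann-Whitney optionally).
#'
#' @param estimates data frame from [detect_wake_times()] (or
#'   [detect_bedtimes()]).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return a `circadian_summary`: list with `n`, `n_censored`, `mean`, `sd`,
#'   quantiles `q05,q25,q50,q75,q95`, per-stratum weekday/weekend `mean`/
#'   `sd`/`n`, and the comparison `statistic` and `p_value` (`NA` when a
#'   stratum has fewer than 2 days).
#' @export
summarize_circadian <- function(estimates, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  ok <- !estimates$censored & !is.na(estimates$minutes)
  if (sum(ok) < 2L)
    stop("summarize_circadian: need at least 2 uncensored estimates")
  x <- estimates$minutes[ok]
  wday <- as.POSIXlt(as.Date(estimates$date[ok]))$wday
  weekend <- wday %in% c(0L, 6L)
  qs <- stats::quantile(x, c(.05, .25, .50, .75, .95), names = FALSE)
  cmp <- list(statistic = NA_real_, p_value = NA_real_)
  if (sum(weekend) >= 2L && sum(!weekend) >= 2L) {
    ht <- tryCatch(
      if (test == "welch") stats::t.test(x[!weekend], x[weekend])
      else stats::wilcox.test(x[!weekend], x[weekend], exact = FALSE),
      error = function(e) NULL)  # essentially-constant data
    if (!is.null(ht))
      cmp <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  structure(list(
    home_id = estimates$home_id[1L],
    n = sum(ok), n_censored = sum(!ok),
    mean = mean(x), sd = stats::sd(x),
    q05 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q95 = qs[5],
    weekday = list(n = sum(!weekend), mean = mean(x[!weekend]),
                   sd = stats::sd(x[!weekend])),
    weekend = list(n = sum(weekend),
                   mean = if (any(weekend)) mean(x[weekend]) else NA_real_,
                   sd = if (sum(weekend) > 1) stats::sd(x[weekend]) else NA_real_),
    test = test, statistic = cmp$statistic, p_value = cmp$p_value
  ), class = "circadian_summary")
}

#' @export
print.circadian_summary <- function(x, ...) {
  cat(sprintf("Circadian summary %s: %d days (%d censored)\n",
              x$home_id, x$n + x$n_censored, x$n_censored))
  cat(sprintf("  mean %s, sd %.1f min; median %s [q05 %s, q95 %s]\n",
              fmt_clock((x$mean %% 1440) * 60), x$sd,
              fmt_clock((x$q50 %% 1440) * 60),
              fmt_clock((x$q05 %% 1440) * 60),
              fmt_clock((x$q95 %% 1440) * 60)))
  if (!is.na(x$p_value))
    cat(sprintf("  weekday %s (n=%d) vs weekend %s (n=%d): %s p = %.3f\n",
                fmt_clock((x$weekday$mean %% 1440) * 60), x$weekday$n,
                fmt_clock((x$weekend$mean %% 1440) * 60), x$weekend$n,
                x$test, x$p_value))
  invisible(x)
}
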