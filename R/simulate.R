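# Semi-Markov synthetic-resident simulator.
#
# Each simulated day: wake time W and bed time B are drawn from truncated
# normals (W < B enforced). Outside [W, B) the occupant is in the bedroom,
# emitting sparse night firings plus short "settling" (after B) and "rising"
# (before W) movement bursts. Between W and B the day is partitioned into
# room sojourns drawn from an hour-specific room distribution with lognormal
# dwell times (minimum 5 min); within a sojourn firings form a Poisson
# process at the archetype's hourly intensity, with inter-firing spacing
# floored at the sensor hold time and thinned by the miss probability.
# Sensors are event emitters with hold-time dead zones, not presence
# sensors: a motionless occupant emits nothing.

#' Construct a routine archetype
#'
#' @param name archetype label.
#' @param wake_mu,wake_sigma wake-time mean and sd, minutes after midnight.
#' @param bed_mu,bed_sigma bed-time mean and sd, minutes after midnight.
#' @param hourly_intensity 24 non-negative expected firings/hour while awake.
#' @param room_schedule 24 x 5 matrix (rows = hours, columns =
#'   [room_labels()]), each row a probability distribution over rooms for a
#'   sojourn starting in that hour.
#' @param night_firing_rate expected bedroom firings/hour while asleep.
#' @param dwell_mean named mean sojourn duration per room, minutes.
#' @param dwell_sdlog lognormal sdlog of dwell times.
#' @param wake_range,bed_range truncation bounds, minutes.
#' @return object of class `routine_archetype`.
#' @export
routine_archetype <- function(name, wake_mu, wake_sigma, bed_mu, bed_sigma,
                              hourly_intensity, room_schedule,
                              night_firing_rate = 0.5,
                              dwell_mean = c(bathroom = 8, kitchen = 22,
                                             bedroom = 35, living_room = 40,
                                             other = 25),
                              dwell_sdlog = 0.5,
                              wake_range = c(wake_mu - 120, wake_mu + 180),
                              bed_range = c(bed_mu - 120, bed_mu + 90)) {
  stopifnot(length(hourly_intensity) == 24L, all(hourly_intensity >= 0),
            wake_mu < bed_mu,
            is.matrix(room_schedule), nrow(room_schedule) == 24L,
            ncol(room_schedule) == length(ROOM_LABELS),
            all(room_schedule >= 0),
            all(abs(rowSums(room_schedule) - 1) < 1e-9),
            all(ROOM_LABELS %in% names(dwell_mean)))
  colnames(room_schedule) <- ROOM_LABELS
  structure(list(name = name, wake_mu = wake_mu, wake_sigma = wake_sigma,
                 bed_mu = bed_mu, bed_sigma = bed_sigma,
                 hourly_intensity = as.numeric(hourly_intensity),
                 room_schedule = room_schedule,
                 night_firing_rate = night_firing_rate,
                 dwell_mean = dwell_mean[ROOM_LABELS],
                 dwell_sdlog = dwell_sdlog,
                 wake_range = wake_range, bed_range = bed_range),
            class = "routine_archetype")
}

#' @export
print.routine_archetype <- function(x, ...) {
  cat(sprintf("Routine archetype '%s': wake %s +/- %d min, bed %s +/- %d min, peak hour %d\n",
              x$name, fmt_clock(x$wake_mu * 60), round(x$wake_sigma),
              fmt_clock(x$bed_mu * 60), round(x$bed_sigma),
              which.max(x$hourly_intensity) - 1L))
  invisible(x)
}

#' The two shipped behavioral archetypes
#'
#' Archetype A (`gradual_midday`): later waker whose activity ramps
#' gradually from wake-up to a single early-afternoon maximum (hour 14) and
#' then declines toward 23:00; spends relatively more awake time in the
#' living room. Archetype B (`rapid_morning`): earlier waker with a rapid
#' post-wake surge peaking at hour 9, a plateau until 14:00, a dip, a stable
#' evening level until ~21:30, then decline; spends relatively more time in
#' the bedroom.
#'
#' @return named list with elements `A` and `B` of class
#'   `routine_archetype`.
#' @export
default_archetypes <- function() {
  dwell <- c(bathroom = 8, kitchen = 22, bedroom = 35, living_room = 40,
             other = 25)
  # `share` is the target fraction of awake TIME per room; sojourns are drawn
  # at entry, so the draw probability is share / mean dwell, renormalized
  # (semi-Markov stationary occupation = p * dwell).
  sched <- function(share) {
    m <- matrix(rep(share, each = 24L), nrow = 24L,
                dimnames = list(NULL, ROOM_LABELS))
    # meal-time kitchen emphasis (breakfast 7-9, lunch 12-14, dinner 19-20),
    # taken from the living-room share
    meals <- c(7:9, 12:14, 19:20)
    m[meals + 1L, "kitchen"] <- m[meals + 1L, "kitchen"] + 0.10
    m[meals + 1L, "living_room"] <- m[meals + 1L, "living_room"] - 0.10
    m <- sweep(m, 2L, dwell[ROOM_LABELS], "/")
    m / rowSums(m)
  }
  a_int <- c(0.5, 0.5, 0.5, 0.5, 0.5, 1,   # 0-5: rarely awake
             3, 4, 5, 6, 7, 8.5, 10, 11, 12, 10.5, 9, 7.5,
             6, 5, 4.5, 3.5, 2.5, 1.5)
  b_int <- c(0.5, 0.5, 0.5, 0.5, 0.5, 1,
             5, 9, 12, 13, 11.5, 11.5, 11.5, 11.5, 8, 6.5, 6.5, 6.5,
             6.5, 6.5, 6.5, 6, 3.5, 1.5)
  list(
    A = routine_archetype(
      "gradual_midday",
      wake_mu = 480, wake_sigma = 30, bed_mu = 1350, bed_sigma = 30,
      hourly_intensity = a_int,
      room_schedule = sched(c(bathroom = 0.07, kitchen = 0.18,
                              bedroom = 0.22, living_room = 0.37,
                              other = 0.16)),
      wake_range = c(360, 660), bed_range = c(1230, 1430)),
    B = routine_archetype(
      "rapid_morning",
      wake_mu = 420, wake_sigma = 25, bed_mu = 1380, bed_sigma = 25,
      hourly_intensity = b_int,
      room_schedule = sched(c(bathroom = 0.07, kitchen = 0.16,
                              bedroom = 0.36, living_room = 0.27,
                              other = 0.14)),
      wake_range = c(360, 600), bed_range = c(1260, 1430))
  )
}

#' Expected full-day room fractions of an archetype
#'
#' Analytic stationary expectation of the semi-Markov routine: sleep time
#' goes to the bedroom; awake time is split by the dwell-weighted sojourn
#' probabilities (occupation of a semi-Markov state is proportional to entry
#' probability times mean dwell), averaged over the mean awake window.
#'
#' @param archetype a [routine_archetype()].
#' @return named fractions over [room_labels()], summing to 1.
#' @export
archetype_expected_fractions <- function(archetype) {
  sleep_min <- 1440 - (archetype$bed_mu - archetype$wake_mu)
  awake_min <- 1440 - sleep_min
  hrs <- (floor(archetype$wake_mu / 60):floor((archetype$bed_mu - 1) / 60)) + 1L
  w <- sweep(archetype$room_schedule[hrs, , drop = FALSE], 2L,
             archetype$dwell_mean[ROOM_LABELS], "*")
  p <- colMeans(w / rowSums(w))
  frac <- p * awake_min / 1440
  frac["bedroom"] <- frac["bedroom"] + sleep_min / 1440
  frac
}

rtrunc_norm <- function(mu, sigma, range) {
  repeat {
    x <- stats::rnorm(1L, mu, sigma)
    if (x >= range[1L] && x <= range[2L]) return(x)
  }
}

# Poisson firing times over [from, to) minutes with hour-varying rate,
# spacing floored at hold (minutes). When floor_first, the hold also applies
# to the first waiting time (used after an entry-trigger firing); otherwise
# the first waiting time is purely exponential so expected counts match
# rate x duration. Returns times in minutes.
fire_times <- function(from, to, rate_of_hour, hold_min, floor_first = FALSE) {
  out <- numeric(0)
  t <- from
  while (t < to) {
    lam <- rate_of_hour[(floor(t / 60) %% 24) + 1L]
    if (lam <= 0) { t <- (floor(t / 60) + 1L) * 60; next }
    gap <- stats::rexp(1L, rate = lam / 60)
    t2 <- t + max(gap, if (length(out) || floor_first) hold_min else 0)
    # if the draw crosses an hour boundary into a different rate, re-draw
    # from the boundary (memorylessness makes this exact for the
    # exponential part; the hold floor is carried over)
    if (floor(t2 / 60) > floor(t / 60) &&
        rate_of_hour[(floor(min(t2, to - 1e-9) / 60) %% 24) + 1L] != lam &&
        t2 < to) {
      t <- (floor(t / 60) + 1L) * 60
      next
    }
    if (t2 >= to) break
    out <- c(out, t2)
    t <- t2
  }
  out
}

#' Simulate one day of PIR events for an archetype
#'
#' @param archetype a [routine_archetype()].
#' @param date local calendar date.
#' @param seed integer seed for this day's draws.
#' @param hold sensor hold time, seconds.
#' @param miss_prob probability a movement fails to fire the sensor.
#' @param outing_prob probability of one out-of-home excursion (entrance-door
#'   firings at exit and return, silence in between).
#' @param entry_trigger_prob probability that walking into (and out of) a
#'   room fires its sensor within a few seconds of the transition (default
#'   1: crossing a room is itself movement). Set to 0 for a pure
#'   within-room Poisson process.
#' @param timezone IANA zone.
#' @return list with `events` (data frame `minute`, `room`, minutes after
#'   local midnight, time-sorted), `wake_min`, `bed_min` (planted truth).
#' @export
simulate_day <- function(archetype, date, seed, hold = 60, miss_prob = 0.05,
                         outing_prob = 0.1, entry_trigger_prob = 1,
                         timezone = "UTC") {
  hold_min <- hold / 60
  with_seed(seed, {
    W <- rtrunc_norm(archetype$wake_mu, archetype$wake_sigma,
                     archetype$wake_range)
    B <- rtrunc_norm(archetype$bed_mu, archetype$bed_sigma,
                     archetype$bed_range)
    while (B <= W + 60)
      B <- rtrunc_norm(archetype$bed_mu, archetype$bed_sigma,
                       archetype$bed_range)
    ev_min <- list(); ev_room <- list()
    add <- function(mins, room) {
      if (length(mins)) {
        ev_min[[length(ev_min) + 1L]] <<- mins
        ev_room[[length(ev_room) + 1L]] <<- rep(room, length(mins))
      }
    }
    # night bedroom firings (sparse movement during sleep)
    for (seg in list(c(0, W), c(B, 1440))) {
      n <- stats::rpois(1L, archetype$night_firing_rate *
                          (seg[2L] - seg[1L]) / 60)
      if (n > 0) {
        tt <- sort(stats::runif(n, seg[1L], seg[2L]))
        tt <- tt[c(TRUE, diff(tt) >= hold_min)]
        add(tt, "bedroom")
      }
    }
    # settling burst after bed entry and rising burst before leaving bed
    add(B + sort(stats::runif(stats::rpois(1L, 2) + 1L, 0, 3)), "bedroom")
    rise <- W - sort(stats::runif(stats::rpois(1L, 2) + 1L, 0, 3),
                     decreasing = TRUE)
    add(rise[rise >= 0], "bedroom")
    # daytime sojourns
    t <- W; first <- TRUE
    while (t < B - 1e-9) {
      h <- (floor(t / 60) %% 24) + 1L
      p <- archetype$room_schedule[h, ]
      if (first) { p["bedroom"] <- 0; p <- p / sum(p) }
      room <- sample(ROOM_LABELS, 1L, prob = p)
      mu <- archetype$dwell_mean[[room]]
      dwell <- max(5, stats::rlnorm(1L, log(mu) - archetype$dwell_sdlog^2 / 2,
                                    archetype$dwell_sdlog))
      end <- min(B, t + dwell)
      entered <- entry_trigger_prob > 0 &&
        stats::runif(1L) < entry_trigger_prob
      if (entered) {
        t0 <- t + stats::runif(1L, 0, 10 / 60)
        if (t0 < end) add(t0, room) else entered <- FALSE
      }
      from <- if (entered) t0 else t
      ft <- fire_times(from, end, archetype$hourly_intensity, hold_min,
                       floor_first = entered)
      add(ft, room)
      # walking out is movement too: exit firing from the room being left
      if (entry_trigger_prob > 0 && stats::runif(1L) < entry_trigger_prob) {
        tx <- end - stats::runif(1L, 0, 10 / 60)
        last_fire <- if (length(ft)) ft[length(ft)] else if (entered) t0 else -Inf
        if (tx > last_fire + hold_min) add(tx, room)
      }
      t <- end; first <- FALSE
    }
    minute <- unlist(ev_min, use.names = FALSE)
    room <- unlist(ev_room, use.names = FALSE)
    if (is.null(minute)) { minute <- numeric(0); room <- character(0) }
    # sensor misses
    if (miss_prob > 0 && length(minute)) {
      keep <- stats::runif(length(minute)) >= miss_prob
      minute <- minute[keep]; room <- room[keep]
    }
    # optional outing: silence bracketed by entrance-door firings
    if (stats::runif(1L) < outing_prob && B - 120 > W + 60) {
      o <- stats::runif(1L, W + 60, B - 120)
      dur <- stats::runif(1L, 60, 120)
      keep <- minute < o | minute > o + dur
      minute <- c(minute[keep], o, o + dur)
      room <- c(room[keep], "entrance_door", "entrance_door")
    }
    ord <- order(minute)
    list(events = data.frame(minute = minute[ord], room = room[ord],
                             stringsAsFactors = FALSE),
         wake_min = W, bed_min = B)
  })
}

#' Simulation configuration
#'
#' Defaults reproduce the shipped study conditions: an 18-home cohort (5
#' archetype-A and 13 archetype-B residents) monitored for 60 days with a
#' 60 s sensor hold, a 5% sensor miss probability and roughly one outing
#' every ten days.
#'
#' @param n_days days simulated per participant.
#' @param counts named integer vector of participants per archetype; names
#'   must match `archetypes`.
#' @param archetypes list of [routine_archetype()]s (default
#'   [default_archetypes()]).
#' @param hold sensor hold, seconds.
#' @param miss_prob sensor miss probability in `[0, 1]`.
#' @param outing_prob per-day probability of an out-of-home excursion.
#' @param entry_trigger_prob probability that entering a room fires its
#'   sensor (see [simulate_day()]).
#' @param seed master seed; every draw in the cohort derives from it.
#' @param start_date first monitored date.
#' @param timezone IANA zone for the simulated homes.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_days = 60L, counts = c(A = 5L, B = 13L),
                              archetypes = default_archetypes(),
                              hold = 60, miss_prob = 0.05, outing_prob = 0.1,
                              entry_trigger_prob = 1,
                              seed = 1L, start_date = "2023-06-01",
                              timezone = "UTC") {
  stopifnot(all(names(counts) %in% names(archetypes)),
            all(counts >= 0), sum(counts) >= 1L, n_days >= 1L,
            miss_prob >= 0, miss_prob <= 1,
            outing_prob >= 0, outing_prob <= 1,
            entry_trigger_prob >= 0, entry_trigger_prob <= 1, hold > 0)
  structure(list(n_days = as.integer(n_days), counts = counts,
                 archetypes = archetypes, hold = hold,
                 miss_prob = miss_prob, outing_prob = outing_prob,
                 entry_trigger_prob = entry_trigger_prob,
                 seed = as.integer(seed), start_date = as.Date(start_date),
                 timezone = timezone),
            class = "simulation_config")
}

#' Default layout of a simulated home
#'
#' One PIR sensor per room plus an entrance-door sensor.
#'
#' @param home_id home identifier.
#' @param timezone IANA zone.
#' @return a [home_layout()].
#' @export
default_layout <- function(home_id, timezone = "UTC") {
  sensors <- stats::setNames(SENSOR_LABELS,
                             paste0("pir_", sub("_", "", SENSOR_LABELS)))
  names(sensors)[sensors == "entrance_door"] <- "door_entrance"
  home_layout(home_id, sensors, timezone)
}

#' Generate a synthetic cohort
#'
#' One event log per participant, with the planted ground truth (archetype
#' label, per-day wake and bed times) attached for recovery testing.
#' Deterministic given the config: every participant-day draws from a
#' sub-seed derived from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `pir_cohort`: list with `participants` (each holding `log`,
#'   `layout`, `archetype`, `truth`) and `config`. `truth` is a data frame
#'   `date`, `wake_min`, `bed_min`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- rep(names(config$counts), config$counts)
  dates <- config$start_date + seq_len(config$n_days) - 1L
  participants <- lapply(seq_along(labels), function(i) {
    arch <- config$archetypes[[labels[i]]]
    home_id <- sprintf("home%02d", i)
    layout <- default_layout(home_id, config$timezone)
    room2sensor <- stats::setNames(names(layout$sensors),
                                   unname(layout$sensors))
    days <- lapply(seq_along(dates), function(d)
      simulate_day(arch, dates[d], seed = derive_seed(config$seed, i, d),
                   hold = config$hold, miss_prob = config$miss_prob,
                   outing_prob = config$outing_prob,
                   entry_trigger_prob = config$entry_trigger_prob,
                   timezone = config$timezone))
    mins <- unlist(lapply(seq_along(days), function(d)
      as.numeric(local_midnight(dates[d], config$timezone)) +
        round(days[[d]]$events$minute * 60)), use.names = FALSE)
    rooms <- unlist(lapply(days, function(x) x$events$room),
                    use.names = FALSE)
    if (is.null(mins)) { mins <- numeric(0); rooms <- character(0) }
    # timestamps are rounded to whole seconds; collapse any resulting
    # same-sensor same-second duplicates (a real controller would too)
    dup <- duplicated(data.frame(mins, rooms))
    mins <- mins[!dup]; rooms <- rooms[!dup]
    log <- event_log(as.POSIXct(mins, tz = config$timezone,
                                origin = "1970-01-01"),
                     room2sensor[rooms], rooms, home_id, config$timezone)
    truth <- data.frame(
      date = as.character(dates),
      wake_min = vapply(days, `[[`, numeric(1), "wake_min"),
      bed_min = vapply(days, `[[`, numeric(1), "bed_min"))
    list(log = log, layout = layout, archetype = labels[i], truth = truth)
  })
  structure(list(participants = participants, config = config),
            class = "pir_cohort")
}

#' @export
print.pir_cohort <- function(x, ...) {
  lab <- table(vapply(x$participants, `[[`, character(1), "archetype"))
  cat(sprintf("Synthetic PIR cohort: %d participants (%s), %d days each\n",
              length(x$participants),
              paste(names(lab), lab, sep = "=", collapse = ", "),
              x$config$n_days))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one canonical event CSV and one layout JSON per home, plus a
#' ground-truth CSV (`home_id,date,wake,bed,archetype`).
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- do.call(rbind, lapply(cohort$participants, function(p) {
    write_event_log(p$log, file.path(dir, paste0(p$layout$home_id,
                                                 "_events.csv")))
    write_home_layout(p$layout, file.path(dir, paste0(p$layout$home_id,
                                                      "_layout.json")))
    data.frame(home_id = p$layout$home_id, date = p$truth$date,
               wake = fmt_clock(p$truth$wake_min * 60),
               bed = fmt_clock((p$truth$bed_min %% 1440) * 60),
               archetype = p$archetype)
  }))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
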