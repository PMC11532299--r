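hms <- function(h, m = 0, s = 0) h * 3600 + m * 60 + s

test_that("hourly profile is the per-day mean firing count per hour", {
  # 3 kitchen firings at 10:xx on each of 2 days
  sec <- c(hms(10, 1), hms(10, 20), hms(10, 40),
           86400 + c(hms(10, 5), hms(10, 25), hms(10, 45)))
  log <- make_log(sec, rep("kitchen", 6))
  p <- hourly_activity_profile(log)
  expect_equal(unname(unclass(p)[11]), 3.0)
  expect_equal(sum(p), 3.0)

  # boundary: lone firing at 23:59:59 falls in bin 23
  p2 <- hourly_activity_profile(make_log(hms(23, 59, 59), "bathroom"))
  expect_equal(unname(which(unclass(p2) > 0)), 24L)

  # entrance-door firings never count as activity
  p3 <- hourly_activity_profile(
    make_log(c(hms(9), hms(9, 5)), c("kitchen", "entrance_door")))
  expect_equal(sum(p3), 1.0)

  expect_error(hourly_activity_profile(make_log(hms(9), "entrance_door")),
               "no PIR firings")
})

test_that("profile matches a brute-force per-hour tally on random data", {
  set.seed(13)
  sec <- sort(sample.int(3 * 86400, 500))
  rooms <- sample(room_labels(), 500, replace = TRUE)
  log <- make_log(sec, rooms)
  p <- hourly_activity_profile(log)
  days <- unique(sec %/% 86400)
  tally <- numeric(24)
  for (s in sec) tally[(s %% 86400) %/% 3600 + 1] <-
    tally[(s %% 86400) %/% 3600 + 1] + 1
  expect_equal(as.numeric(p), tally / length(days))
})

test_that("duplicating every monitored day leaves the profile unchanged", {
  set.seed(14)
  sec <- sort(sample.int(86400, 120))
  log1 <- make_log(sec, sample(room_labels(), 120, replace = TRUE))
  log2 <- make_log(c(sec, sec + 86400), rep(log1$room, 2))
  expect_equal(unclass(hourly_activity_profile(log1)),
               unclass(hourly_activity_profile(log2)),
               ignore_attr = TRUE)
})

test_that("population curve: degenerate cases and percentile oracle", {
  p <- rep(1:2, 12)
  same <- population_curve(list(p, p, p))
  expect_equal(unname(same$mean), p)
  expect_equal(unname(same$q1), p)
  expect_equal(unname(same$q3), p)

  two <- population_curve(list(rep(0, 24), rep(2, 24)))
  expect_equal(unname(two$mean), rep(1, 24))

  set.seed(15)
  m <- matrix(rexp(7 * 24), nrow = 7)
  pc <- population_curve(m)
  # sort-based linear interpolation oracle for the quartiles (type 7)
  for (b in c(1, 12, 24)) {
    x <- sort(m[, b])
    h <- (7 - 1) * 0.25 + 1
    expect_equal(unname(pc$q1[b]),
                 x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)]))
  }
  expect_true(all(pc$q1 <= pc$q3))
})

test_that("population curve of n copies of one profile is that profile", {
  set.seed(16)
  p <- rexp(24)
  pc <- population_curve(do.call(rbind, replicate(5, p, simplify = FALSE)))
  expect_equal(unname(pc$mean), p)
})

test_that("room fractions: whole-span interval, mixed day, conservation", {
  mk_tl <- function(rooms, starts_h, ends_h) {
    base <- as.POSIXct("2023-06-01", tz = "UTC")
    occupancy_timeline(
      data.frame(room = rooms, start = base + starts_h * 3600,
                 end = base + ends_h * 3600, basis = "observed"),
      "h1", unknown_time = 86400 - sum(ends_h - starts_h) * 3600,
      span_start = base, span_end = base + 86400)
  }
  tl <- mk_tl("bedroom", 0, 24)
  fr <- room_occupancy_fractions(tl)
  expect_equal(unname(fr["bedroom"]), 1.0)

  # bedroom 13 h, living 6 h, kitchen 3 h, bathroom 2 h of a 24 h day
  tl <- mk_tl(c("bedroom", "living_room", "kitchen", "bathroom"),
              c(0, 13, 19, 22), c(13, 19, 22, 24))
  fr <- room_occupancy_fractions(tl)
  expect_equal(unname(fr[c("bedroom", "living_room", "kitchen", "bathroom")]),
               c(13, 6, 3, 2) / 24)
  expect_gt(fr["bedroom"], 0.5)

  set.seed(17)
  for (i in 1:5) {
    tl <- infer_presence(random_log(40), hold = 60)
    expect_equal(sum(room_occupancy_fractions(tl)), 1, tolerance = 1e-9)
  }
})

test_that("hourly room usage clips intervals at hour boundaries", {
  base <- as.POSIXct("2023-06-01", tz = "UTC")
  # bedroom 22:00-06:00 on each of 3 nights (span 4 calendar days)
  iv <- do.call(rbind, lapply(0:2, function(d)
    data.frame(room = "bedroom", start = base + d * 86400 + 22 * 3600,
               end = base + (d + 1) * 86400 + 6 * 3600, basis = "observed")))
  tl <- occupancy_timeline(iv, "h1", 0, base, base + 4 * 86400 - 1)
  u <- hourly_room_usage(tl, n_days = 3)
  expect_equal(unname(u["bedroom", c(23, 24, 1:6)]), rep(60, 8))
  expect_equal(sum(u["bedroom", 7:22]), 0)

  # 10:30-11:15 on one of two days
  tl2 <- occupancy_timeline(
    data.frame(room = "kitchen", start = base + hms(10, 30),
               end = base + hms(11, 15), basis = "observed"),
    "h1", 0, base, base + 2 * 86400 - 1)
  u2 <- hourly_room_usage(tl2, n_days = 2)
  expect_equal(unname(u2["kitchen", 11]), 15)
  expect_equal(unname(u2["kitchen", 12]), 7.5)
  expect_true(all(u2 >= 0 & u2 <= 60))
})

test_that("hourly room usage equals a minute-resolution accumulation oracle", {
  set.seed(18)
  log <- random_log(80, span_sec = 2 * 86400)
  tl <- infer_presence(log, hold = 300)
  n_days <- 2L
  u <- hourly_room_usage(tl, n_days = n_days)
  # oracle: walk the timeline in 1-second steps, accumulate per hour bin
  acc <- matrix(0, length(room_labels()), 24,
                dimnames = list(room_labels(), NULL))
  t0 <- as.numeric(as.POSIXct("2023-06-01", tz = "UTC"))
  for (i in seq_len(nrow(tl))) {
    secs <- seq(as.numeric(tl$start[i]), as.numeric(tl$end[i]) - 1)
    h <- ((secs - t0) %% 86400) %/% 3600 + 1
    for (b in unique(h))
      acc[tl$room[i], b] <- acc[tl$room[i], b] + sum(h == b) / 60
  }
  expect_equal(u, acc / n_days, tolerance = 1e-9, ignore_attr = TRUE)
})
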