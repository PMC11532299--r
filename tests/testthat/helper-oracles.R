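# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately naive (second-by-second scans, direct formula
# evaluation) and share no code with the implementation they check.

# Build an event_log from second offsets relative to a base midnight.
make_log <- function(sec, rooms, home_id = "h1", tz = "UTC",
                     base = "2023-06-01") {
  ord <- order(sec)
  ts <- as.POSIXct(paste0(base, " 00:00:00"), tz = tz) + sec[ord]
  event_log(ts, paste0("s_", rooms[ord], recycle0 = TRUE), rooms[ord],
            home_id, tz)
}

# Random event log on an integer-second grid.
random_log <- function(n_events, n_rooms = 4, span_sec = 7200,
                       door_prob = 0.1, base = "2023-06-01") {
  rooms <- sample(room_labels()[seq_len(n_rooms)], n_events, replace = TRUE)
  door <- runif(n_events) < door_prob
  rooms[door] <- "entrance_door"
  sec <- sort(sample.int(span_sec, n_events))
  make_log(sec, rooms, base = base)
}

# Second-by-second brute-force presence oracle. Returns, for each second in
# [t1, tn + hold), the attributed room label or "unknown". Events must sit
# on an integer-second grid.
brute_presence <- function(sec, rooms, hold, max_fill_gap = Inf) {
  n <- length(sec)
  grid <- seq(sec[1L], sec[n] + hold - 1L)
  prev <- findInterval(grid, sec)
  out <- character(length(grid))
  for (g in seq_along(grid)) {
    i <- prev[g]
    s <- grid[g]
    if (rooms[i] == "entrance_door") { out[g] <- "unknown"; next }
    if (s < sec[i] + hold) { out[g] <- rooms[i]; next }
    filled <- i < n && rooms[i + 1L] == rooms[i] &&
      rooms[i + 1L] != "entrance_door" &&
      (sec[i + 1L] - sec[i]) <= max_fill_gap
    out[g] <- if (filled) rooms[i] else "unknown"
  }
  out
}

# Expand an occupancy_timeline to the same per-second representation.
timeline_seconds <- function(tl) {
  t0 <- as.numeric(attr(tl, "span_start"))
  t1 <- as.numeric(attr(tl, "span_end"))
  out <- rep("unknown", t1 - t0)
  for (i in seq_len(nrow(tl))) {
    a <- as.numeric(tl$start[i]) - t0
    b <- as.numeric(tl$end[i]) - t0
    if (b > a) out[(a + 1L):b] <- tl$room[i]
  }
  out
}

# Direct per-point silhouette evaluation (loops, no shared code).
silhouette_by_hand <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    dists <- sqrt(rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
    mine <- which(labels == labels[i] & seq_len(n) != i)
    if (length(mine) == 0L) { s[i] <- 0; next }
    a <- mean(dists[mine])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(dists[labels == l]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Tight 24-d Gaussian blobs around given centers; for cluster recovery.
blob_profiles <- function(centers, n_per, noise_sd = 0.05) {
  m <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j)
    matrix(rep(centers[j, ], each = n_per), nrow = n_per) +
      matrix(rnorm(n_per * ncol(centers), sd = noise_sd), nrow = n_per)))
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("h%02d", 0:23)
  m
}
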