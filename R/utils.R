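#' @keywords internal
"_PACKAGE"

# Rooms that carry a PIR sensor and can hold an occupant. "entrance_door" is a
# boundary sensor: it fires, but never receives occupancy.
ROOM_LABELS <- c("bathroom", "kitchen", "bedroom", "living_room", "other")
SENSOR_LABELS <- c(ROOM_LABELS, "entrance_door")

#' Valid room labels
#'
#' @param include_door if `TRUE`, include the `entrance_door` boundary sensor
#'   label alongside the five occupiable rooms.
#' @return character vector of canonical labels.
#' @export
room_labels <- function(include_door = FALSE) {
  if (include_door) SENSOR_LABELS else ROOM_LABELS
}

#' Round half away from zero
#'
#' Reported summary values use commercial (half-up) rounding rather than the
#' IEEE round-half-even of [base::round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Population standard deviation (divisor N)
#'
#' @param x numeric vector.
#' @return `sqrt(mean((x - mean(x))^2))`.
#' @export
pop_sd <- function(x) {
  if (length(x) == 0L) stop("pop_sd: empty input")
  sqrt(mean((x - mean(x))^2))
}

# Derive a stream-specific sub-seed from a master seed and integer indices so
# that each participant/day/restart has its own reproducible RNG stream.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Parse "HH:MM" / "HH:MM:SS" clock strings to seconds after midnight.
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.double(p)
    if (any(is.na(p)) || length(p) < 2L || length(p) > 3L)
      stop("invalid clock time: expected HH:MM[:SS]")
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

fmt_clock <- function(sec) {
  sec <- round(sec)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}
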