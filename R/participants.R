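# Participant table handling: cohort inclusion filtering and the demographic
# summary reported for a monitored cohort.

#' Read a participant table
#'
#' CSV with header `age,gender,days`: one row per monitored home. Gender is
#' normalized to `F`/`M` (case-insensitive, `female`/`male` accepted).
#'
#' @param path CSV path.
#' @return data frame with columns `home_id`, `age`, `gender`, `days`.
#' @export
read_participant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "gender", "days")
  if (!all(need %in% names(df)))
    stop("parse error: expected columns ", paste(need, collapse = ","))
  if (nrow(df) == 0L)
    return(data.frame(home_id = character(), age = integer(),
                      gender = character(), days = integer()))
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age))
    stop("parse error: non-numeric age at row ", which(is.na(age))[1L])
  g <- toupper(substr(trimws(df$gender), 1L, 1L))
  if (any(!g %in% c("F", "M")))
    stop("parse error: gender must be F/M (got '",
         df$gender[which(!g %in% c("F", "M"))[1L]], "')")
  days <- suppressWarnings(as.integer(df$days))
  if (anyNA(days) || any(days < 1L))
    stop("parse error: days must be integers >= 1")
  home_id <- if ("home_id" %in% names(df)) as.character(df$home_id)
             else sprintf("home%02d", seq_len(nrow(df)))
  data.frame(home_id = home_id, age = as.integer(age), gender = g,
             days = days, stringsAsFactors = FALSE)
}

#' Reference participant table
#'
#' The 18-participant demographic table (age, gender, days monitored) of the
#' Chilean single-occupant elderly cohort whose monitoring conditions this
#' package's defaults emulate: 15 women and 3 men aged 61-89, monitored for
#' 40-83 days each.
#'
#' @return data frame as from [read_participant_table()].
#' @export
example_participants <- function() {
  read_participant_table(
    system.file("extdata", "participants.csv", package = "pirroutines",
                mustWork = TRUE))
}

#' Apply cohort inclusion criteria
#'
#' The monitored cohort is restricted to older adults: records below the
#' minimum age are dropped, order preserved. (Other criteria of the study
#' design — living alone, no severe impairment, no pets — are decided at
#' recruitment and are not representable in the table.)
#'
#' @param records participant data frame.
#' @param min_age inclusive minimum age in years (default 60).
#' @return filtered data frame.
#' @export
apply_inclusion_criteria <- function(records, min_age = 60) {
  records[records$age >= min_age, , drop = FALSE]
}

#' Demographic summary of a participant table
#'
#' Means and standard deviations of age, overall and per gender. Standard
#' deviations use the population convention (divisor N), and reported values
#' are rounded half-up to one decimal — the convention under which the
#' reference cohort's printed summary is reproduced exactly.
#'
#' @param records participant data frame with `age` and `gender`.
#' @return object of class `demographic_summary`: a list with counts
#'   (`n_total`, `n_female`, `n_male`) and per-group `mean_age_*` / `sd_age_*`
#'   (`NA` when a subgroup is absent).
#' @export
demographic_summary <- function(records) {
  if (nrow(records) == 0L) stop("demographic_summary: empty input")
  grp <- function(x) {
    if (length(x) == 0L) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = round_half_up(mean(x), 1), sd = round_half_up(pop_sd(x), 1))
  }
  all <- grp(records$age)
  f <- grp(records$age[records$gender == "F"])
  m <- grp(records$age[records$gender == "M"])
  structure(list(
    n_total = nrow(records),
    n_female = sum(records$gender == "F"),
    n_male = sum(records$gender == "M"),
    mean_age_all = all[["mean"]], sd_age_all = all[["sd"]],
    mean_age_female = f[["mean"]], sd_age_female = f[["sd"]],
    mean_age_male = m[["mean"]], sd_age_male = m[["sd"]]
  ), class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("Cohort: n = %d (%d F, %d M)\n", x$n_total, x$n_female, x$n_male))
  cat(sprintf("Age: %.1f +/- %.1f (F %.1f +/- %.1f, M %.1f +/- %.1f)\n",
              x$mean_age_all, x$sd_age_all, x$mean_age_female,
              x$sd_age_female, x$mean_age_male, x$sd_age_male))
  invisible(x)
}

#' @export
as.data.frame.demographic_summary <- function(x, ...) {
  data.frame(group = c("all", "female", "male"),
             n = c(x$n_total, x$n_female, x$n_male),
             mean_age = c(x$mean_age_all, x$mean_age_female, x$mean_age_male),
             sd_age = c(x$sd_age_all, x$sd_age_female, x$sd_age_male))
}
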