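#' Default hourly weight profile of ED arrivals
#'
#' A 24-vector of non-negative weights summing to one that fixes how a day's
#' arrivals are spread over the clock. The default encodes the arrival pattern
#' of a community ED whose evening is the busy period: 60% of the daily mass
#' falls on hours 17--23, the maximum sits on hours 20--22 and the minimum on
#' hours 04--05, with a smooth ramp through the morning and afternoon.
#'
#' @return Numeric vector of length 24 (hours 0--23) summing to 1.
#' @export
default_hour_weights <- function() {
  w <- c(0.022, 0.015, 0.010, 0.007, 0.005, 0.005, 0.008, 0.012,
         0.020, 0.026, 0.030, 0.036, 0.036, 0.037, 0.039, 0.042,
         0.050, 0.065, 0.075, 0.090, 0.100, 0.100, 0.100, 0.070)
  w / sum(w)
}

#' Default weekday weight profile of ED arrivals
#'
#' Each weekday carries 13% and each weekend day 19% of the weekly arrivals;
#' since those shares total 103%, they are renormalized to sum to one, giving
#' a weekend share of arrivals of about 36.9%.
#'
#' @return Numeric vector of length 7 (Monday--Sunday) summing to 1.
#' @export
default_weekday_weights <- function() {
  w <- c(rep(0.13, 5), rep(0.19, 2))
  w / sum(w)
}

#' Default holiday calendar
#'
#' Fourteen fixed month-day dates per year standing in for a national
#' official-plus-religious holiday list, chosen to be balanced across the four
#' seasons so the holiday-hour rate uplift is not confounded with season.
#'
#' @return Character vector of `"mm-dd"` strings.
#' @export
default_holidays <- function() {
  c("01-01", "12-25", "12-31",                   # winter
    "03-21", "04-23", "05-01", "05-19",          # spring
    "06-15", "07-15", "08-30",                   # summer
    "09-10", "10-06", "10-29", "11-10")          # fall
}

#' Calendar configuration for the synthetic arrival generator
#'
#' Bundles every knob of the nonhomogeneous Poisson arrival-rate model:
#' the mean daily volume, the within-day and within-week weight profiles,
#' multiplicative season and holiday effects, the holiday calendar, and an
#' optional negative-binomial overdispersion parameter.
#'
#' Season effects follow the meteorological calendar (winter = Dec--Feb,
#' spring = Mar--May, summer = Jun--Aug, fall = Sep--Nov). The default
#' multipliers keep winter and summer at 1.0, put fall 13% below winter and
#' spring at the midpoint 0.93. The default holiday multiplier is the ratio of
#' the holiday to the normal-day hourly arrival rate, 5.45/3.31.
#'
#' @param base_daily_mean Mean arrivals per day over a non-holiday year
#'   (default 75).
#' @param hour_weights 24 non-negative weights (renormalized to sum 1).
#' @param weekday_weights 7 non-negative weights, Monday first (renormalized).
#' @param season_multipliers Named positive multipliers for
#'   `winter`, `spring`, `summer`, `fall`.
#' @param holiday_multiplier Positive multiplier applied to all hours of a
#'   holiday date.
#' @param holidays Character vector of `"mm-dd"` holiday dates.
#' @param dispersion Overdispersion of hourly counts; 0 gives Poisson counts,
#'   any positive value negative-binomial counts with variance
#'   `mu + dispersion * mu^2`.
#'
#' @return An object of class `calendar_config` (a named list).
#' @examples
#' cfg <- calendar_config()
#' cfg$base_daily_mean
#' @export
calendar_config <- function(base_daily_mean = 75,
                            hour_weights = default_hour_weights(),
                            weekday_weights = default_weekday_weights(),
                            season_multipliers = c(winter = 1.0, spring = 0.93,
                                                   summer = 1.0, fall = 0.87),
                            holiday_multiplier = 5.45 / 3.31,
                            holidays = default_holidays(),
                            dispersion = 0) {
  if (base_daily_mean < 0) abort("`base_daily_mean` must be >= 0.")
  if (length(hour_weights) != 24 || any(hour_weights < 0)) {
    abort("`hour_weights` must be 24 non-negative values.")
  }
  if (length(weekday_weights) != 7 || any(weekday_weights < 0)) {
    abort("`weekday_weights` must be 7 non-negative values.")
  }
  if (sum(hour_weights) <= 0 || sum(weekday_weights) <= 0) {
    abort("weight vectors must have positive sum.")
  }
  needed <- c("winter", "spring", "summer", "fall")
  if (!all(needed %in% names(season_multipliers)) ||
      any(season_multipliers[needed] <= 0)) {
    abort("`season_multipliers` must name positive winter/spring/summer/fall factors.")
  }
  if (holiday_multiplier <= 0) abort("`holiday_multiplier` must be > 0.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (length(holidays) && !all(grepl("^\\d{2}-\\d{2}$", holidays))) {
    abort("`holidays` must be 'mm-dd' strings.")
  }
  structure(
    list(
      base_daily_mean = base_daily_mean,
      hour_weights = hour_weights / sum(hour_weights),
      weekday_weights = weekday_weights / sum(weekday_weights),
      season_multipliers = season_multipliers[needed],
      holiday_multiplier = holiday_multiplier,
      holidays = holidays,
      dispersion = dispersion
    ),
    class = "calendar_config"
  )
}

#' @export
print.calendar_config <- function(x, ...) {
  cat("<calendar_config>\n")
  cat("  base daily mean :", x$base_daily_mean, "arrivals/day\n")
  cat("  evening share   :",
      sprintf("%.1f%%", 100 * sum(x$hour_weights[18:24])), "(hours 17-23)\n")
  cat("  weekend share   :",
      sprintf("%.1f%%", 100 * sum(x$weekday_weights[6:7])), "\n")
  cat("  season mult.    :",
      paste(names(x$season_multipliers), x$season_multipliers,
            sep = "=", collapse = ", "), "\n")
  cat("  holiday mult.   :", sprintf("%.3f", x$holiday_multiplier),
      sprintf("(%d dates/yr)", length(x$holidays)), "\n")
  cat("  dispersion      :", x$dispersion, "\n")
  invisible(x)
}

# Meteorological season of a Date vector.
season_of <- function(date) {
  m <- lubridate::month(date)
  dplyr::case_when(
    m %in% c(12, 1, 2) ~ "winter",
    m %in% 3:5         ~ "spring",
    m %in% 6:8         ~ "summer",
    TRUE               ~ "fall"
  )
}

# Holiday flag for a Date vector given "mm-dd" strings.
is_holiday <- function(date, holidays) {
  format(date, "%m-%d") %in% holidays
}

# Hourly calendar skeleton: one row per hour of the horizon.
calendar_grid <- function(horizon, start_date) {
  start_date <- as.Date(start_date)
  ts <- as.POSIXct(start_date, tz = "UTC") + 3600 * (seq_len(horizon) - 1)
  date <- as.Date(ts, tz = "UTC")
  tibble(
    timestamp = ts,
    date = date,
    hour_of_day = lubridate::hour(ts),
    day_of_week = lubridate::wday(date, week_start = 1),
    season = season_of(date)
  ) %>%
    mutate(weekend_flag = .data$day_of_week >= 6)
}
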