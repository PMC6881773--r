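#' Build an hourly arrival-rate profile
#'
#' Composes the expected arrivals-per-hour \eqn{\lambda(t)} of a
#' nonhomogeneous Poisson process from the calendar configuration:
#' \deqn{\lambda(t) \propto hw(h_t)\, wd(d_t)\, sm(s_t)\, hm^{[holiday]}}
#' where `hw` is the hour-of-day weight, `wd` the weekday weight, `sm` the
#' season multiplier and `hm` the holiday multiplier. The profile is
#' renormalized so that its grand mean over a whole non-holiday year equals
#' `base_daily_mean / 24`, i.e. holidays add volume on top of the configured
#' daily mean rather than being absorbed into it.
#'
#' @param config A [calendar_config()].
#' @param horizon Number of hours (>= 1).
#' @param start_date First date of the horizon (midnight start).
#' @return A tibble of class `rate_profile` with one row per hour: `timestamp`,
#'   `date`, `hour_of_day`, `day_of_week`, `weekend_flag`, `season`,
#'   `holiday_flag`, `rate`.
#' @examples
#' prof <- build_rate_profile(calendar_config(), horizon = 48, "2017-01-01")
#' mean(prof$rate)
#' @export
build_rate_profile <- function(config, horizon, start_date = "2017-01-01") {
  stopifnot(inherits(config, "calendar_config"))
  if (horizon < 1) abort("`horizon` must be >= 1 hour.")

  grid <- calendar_grid(horizon, start_date) %>%
    mutate(holiday_flag = is_holiday(.data$date, config$holidays))

  # Normalization constant: mean relative factor over one reference year
  # starting at start_date, holidays switched off.
  ref <- calendar_grid(365L * 24L, start_date)
  norm <- mean(rate_factor(ref, config))

  grid %>%
    mutate(
      rate = config$base_daily_mean / 24 * rate_factor(grid, config) / norm *
        ifelse(.data$holiday_flag, config$holiday_multiplier, 1)
    ) %>%
    structure(class = c("rate_profile", class(tibble())))
}

# Relative (holiday-free) rate factor of a calendar grid; 1 on average for
# uniform weights and unit multipliers.
rate_factor <- function(grid, config) {
  24 * config$hour_weights[grid$hour_of_day + 1L] *
    7 * config$weekday_weights[grid$day_of_week] *
    unname(config$season_multipliers[grid$season])
}

#' Draw hourly arrival counts from a rate profile
#'
#' Counts are independent across hours: Poisson with mean \eqn{\lambda(t)}
#' when `dispersion = 0`, otherwise negative binomial with the same mean and
#' variance \eqn{\mu + \phi\mu^2}.
#'
#' @param profile A `rate_profile` (or numeric vector of hourly rates).
#' @param dispersion Overdispersion \eqn{\phi \ge 0}; 0 gives Poisson.
#' @param seed Integer RNG seed.
#' @return Integer vector of counts, one per hour of the profile.
#' @export
generate_counts <- function(profile, dispersion = 0, seed = 1L) {
  rates <- if (is.data.frame(profile)) profile$rate else as.numeric(profile)
  if (any(rates < 0)) abort("rates must be >= 0.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  n <- length(rates)
  with_local_seed(seed, {
    if (dispersion == 0) {
      rpois(n, rates)
    } else {
      out <- integer(n)
      pos <- rates > 0
      out[pos] <- rnbinom(sum(pos), size = 1 / dispersion, mu = rates[pos])
      out
    }
  })
}

#' Generate a 3-hourly weather series
#'
#' Temperature follows a seasonal sinusoid (annual cycle peaking in late July)
#' plus a damped diurnal sinusoid peaking mid-afternoon, with Gaussian noise;
#' relative humidity is anticorrelated with the temperature anomaly and
#' clipped to \[0, 100\]. Observations are emitted only at hours divisible by
#' three, mirroring a weather station's 3-hour reporting cadence.
#'
#' @param horizon Horizon in hours (>= 3).
#' @param start_date First date of the horizon.
#' @param seed Integer RNG seed.
#' @param mean_temp,annual_amp,peak_yday Annual mean temperature (deg C),
#'   half-amplitude of the annual cycle, and day-of-year of the warm peak.
#' @param diurnal_amp Half-amplitude of the within-day cycle (deg C).
#' @param temp_noise_sd Std. dev. of temperature noise (deg C); 0 gives the
#'   exact sinusoid.
#' @param humid_mean,humid_slope,humid_noise_sd Mean humidity (%), humidity
#'   drop per deg C of temperature anomaly, and humidity noise std. dev.
#' @return Tibble with `timestamp`, `hour`, `temperature`, `humidity`, one row
#'   per 3-hourly observation.
#' @export
generate_weather <- function(horizon, start_date = "2017-01-01", seed = 1L,
                             mean_temp = 19, annual_amp = 9.5, peak_yday = 205,
                             diurnal_amp = 4, temp_noise_sd = 2.5,
                             humid_mean = 65, humid_slope = 1.2,
                             humid_noise_sd = 6) {
  if (horizon < 3) abort("`horizon` must be >= 3 hours.")
  hours <- seq(0L, horizon - 1L, by = 3L)
  ts <- as.POSIXct(as.Date(start_date), tz = "UTC") + 3600 * hours
  yday <- lubridate::yday(ts)
  hod <- lubridate::hour(ts)
  base <- mean_temp +
    annual_amp * cos(2 * pi * (yday - peak_yday) / 365.25) +
    diurnal_amp * cos(2 * pi * (hod - 14) / 24)
  with_local_seed(seed, {
    temp <- base + rnorm(length(hours), 0, temp_noise_sd)
    hum <- humid_mean - humid_slope * (temp - mean_temp) +
      rnorm(length(hours), 0, humid_noise_sd)
  })
  tibble(
    timestamp = ts,
    hour = hours,
    temperature = temp,
    humidity = pmin(100, pmax(0, hum))
  )
}

#' Expand hourly counts into individual arrival times
#'
#' Each hour with count `k` receives `k` arrival instants uniform within that
#' hour; the output is globally sorted, so the per-hour histogram of the
#' result reproduces the count sequence exactly.
#'
#' @param counts Integer vector of hourly counts (hour 0 first).
#' @param seed Integer RNG seed.
#' @return Numeric vector of arrival times in hours since the start of the
#'   count grid, sorted ascending.
#' @export
generate_arrival_times <- function(counts, seed = 1L) {
  counts <- as.integer(counts)
  if (length(counts) == 0) return(numeric(0))
  if (any(is.na(counts)) || any(counts < 0)) abort("counts must be >= 0.")
  hour_idx <- rep.int(seq_along(counts) - 1L, counts)
  with_local_seed(seed, {
    offs <- runif(length(hour_idx))
  })
  structure(sort(hour_idx + offs), hours = length(counts))
}

#' Generate a synthetic hourly ED arrival dataset
#'
#' One-stop generator: builds the default rate profile, draws hourly counts,
#' generates 3-hourly weather, forward-fills it to the hourly grid, and
#' returns one observation per hour with all calendar covariates.
#'
#' @param config A [calendar_config()].
#' @param horizon Horizon in hours (default one non-leap year).
#' @param start_date First date.
#' @param seed Integer master seed; count, weather and any downstream draws
#'   use sub-seeds derived from it.
#' @return Tibble of class `ed_observations`: `timestamp`, `hour_of_day`,
#'   `day_of_week`, `weekend_flag`, `season`, `holiday_flag`, `temperature`,
#'   `humidity`, `count`.
#' @examples
#' obs <- generate_observations(calendar_config(), horizon = 24 * 14, seed = 7)
#' sum(obs$count)
#' @export
generate_observations <- function(config = calendar_config(),
                                  horizon = 365L * 24L,
                                  start_date = "2017-01-01",
                                  seed = 1L) {
  seeds <- derive_seeds(seed, 2)
  profile <- build_rate_profile(config, horizon, start_date)
  counts <- generate_counts(profile, dispersion = config$dispersion,
                            seed = seeds[1])
  weather <- generate_weather(horizon, start_date, seed = seeds[2])
  hourly_weather <- forward_fill_weather(weather, horizon)
  profile %>%
    mutate(
      temperature = hourly_weather$temperature,
      humidity = hourly_weather$humidity,
      count = counts
    ) %>%
    select("timestamp", "hour_of_day", "day_of_week", "weekend_flag",
           "season", "holiday_flag", "temperature", "humidity", "count") %>%
    structure(class = c("ed_observations", class(tibble())))
}

# Scoped RNG: evaluates `code` under `seed` and restores the caller's RNG
# state afterwards, so generator calls never perturb the session stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# k reproducible sub-seeds (< 2^31) derived from a master seed.
derive_seeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max, k))
}
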