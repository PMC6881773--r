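#' Forward-fill a 3-hourly weather series onto the hourly grid
#'
#' Every hour receives the most recent weather observation at or before it
#' (e.g. the 03:00 reading also serves 04:00 and 05:00). Hours before the
#' first observation are back-filled from that first observation, which only
#' ever applies at the head of the series.
#'
#' @param weather Tibble with an `hour` column (hours since series start,
#'   multiples of 3) plus `temperature` and `humidity`.
#' @param horizon Number of hours to cover.
#' @return Tibble with one row per hour 0..horizon-1: `hour`, `temperature`,
#'   `humidity`; no missing values.
#' @export
forward_fill_weather <- function(weather, horizon) {
  stopifnot(all(c("hour", "temperature", "humidity") %in% names(weather)))
  if (any(weather$hour %% 3 != 0)) {
    abort("weather observations must sit at hours divisible by 3.")
  }
  tibble(hour = 0:(horizon - 1)) %>%
    left_join(weather %>% select("hour", "temperature", "humidity"),
              by = "hour") %>%
    tidyr::fill("temperature", "humidity", .direction = "downup")
}

# Slot key of the running mean-arrival-rate feature: hour of day crossed with
# day type (weekday / weekend / holiday). Holiday dominates weekend.
slot_key <- function(hour_of_day, weekend_flag, holiday_flag) {
  day_type <- ifelse(holiday_flag, "holiday",
                     ifelse(weekend_flag, "weekend", "weekday"))
  paste(hour_of_day, day_type, sep = ":")
}

# Causal running mean of past counts sharing the row's slot key.
# Cold start (no earlier same-slot row): global mean of all earlier counts;
# the very first row gets 0.
running_slot_mean <- function(counts, slots) {
  n <- length(counts)
  if (n == 0) return(numeric(0))
  idx <- seq_len(n)
  within <- stats::ave(counts, slots, FUN = function(x) {
    k <- seq_along(x)
    c(NA_real_, (cumsum(x) / k)[-length(x)])
  })
  global_past <- c(0, cumsum(counts)[-n]) / pmax(idx - 1, 1)
  out <- ifelse(is.na(within), global_past, within)
  out[1] <- 0
  out
}

#' Build the model-ready feature table
#'
#' Turns contiguous hourly observations into one row per hour (or per day)
#' holding the calendar and weather covariates, the causal running
#' mean-arrival-rate feature, and the target `count`. The mean arrival rate at
#' hour *t* is the mean of counts at all *earlier* hours sharing *t*'s slot
#' (hour of day crossed with weekday/weekend/holiday day type); it therefore
#' updates itself as time passes and never looks at the present or future.
#'
#' In daily mode counts are summed per day and the hour-dependent columns
#' (`hour_of_day`, `mean_arrival_rate`) are dropped, weather is averaged over
#' the day.
#'
#' @param observations An `ed_observations` tibble (see
#'   [generate_observations()] or [read_observations()]).
#' @param granularity `"hourly"` (default) or `"daily"`.
#' @return Tibble of class `ed_features`. Hourly mode has feature columns
#'   `hour_of_day`, `day_of_week`, `weekend_flag`, `season`, `holiday_flag`,
#'   `temperature`, `humidity`, `mean_arrival_rate` and target `count`; daily
#'   mode drops `hour_of_day` and `mean_arrival_rate`.
#' @export
build_feature_table <- function(observations,
                                granularity = c("hourly", "daily")) {
  granularity <- match.arg(granularity)
  obs <- as_tibble(observations)
  req <- c("timestamp", "hour_of_day", "day_of_week", "weekend_flag",
           "season", "holiday_flag", "temperature", "humidity", "count")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols)) {
    abort(paste("observations lack columns:",
                paste(missing_cols, collapse = ", ")))
  }
  check_hour_contiguous(obs$timestamp)
  if (anyNA(obs[req])) abort("observations contain missing values.")

  if (granularity == "hourly") {
    out <- obs %>%
      mutate(
        season = season_code(.data$season),
        mean_arrival_rate = running_slot_mean(
          .data$count,
          slot_key(.data$hour_of_day, .data$weekend_flag, .data$holiday_flag)
        )
      ) %>%
      select("timestamp", "hour_of_day", "day_of_week", "weekend_flag",
             "season", "holiday_flag", "temperature", "humidity",
             "mean_arrival_rate", "count")
  } else {
    out <- obs %>%
      mutate(date = as.Date(.data$timestamp, tz = "UTC")) %>%
      group_by(.data$date) %>%
      summarise(
        day_of_week = .data$day_of_week[1],
        weekend_flag = .data$weekend_flag[1],
        season = season_code(.data$season[1]),
        holiday_flag = any(.data$holiday_flag),
        temperature = mean(.data$temperature),
        humidity = mean(.data$humidity),
        count = sum(.data$count),
        .groups = "drop"
      )
  }
  structure(out, class = c("ed_features", class(tibble())))
}

# Integer coding of the season categorical (model adapters may one-hot).
season_code <- function(season) {
  if (is.numeric(season)) return(as.integer(season))
  match(season, c("winter", "spring", "summer", "fall"))
}

# Reject gaps in the hourly grid, reporting the first missing range.
check_hour_contiguous <- function(timestamp) {
  if (length(timestamp) < 2) return(invisible(TRUE))
  d <- as.numeric(difftime(timestamp[-1], timestamp[-length(timestamp)],
                           units = "hours"))
  bad <- which(abs(d - 1) > 1e-9)
  if (length(bad)) {
    abort(sprintf(
      "hourly grid has a gap between %s and %s (rows %d-%d).",
      format(timestamp[bad[1]]), format(timestamp[bad[1] + 1]),
      bad[1], bad[1] + 1
    ))
  }
  invisible(TRUE)
}

#' Feature columns of a feature table
#'
#' @param table An `ed_features` tibble.
#' @return Character vector of the candidate predictor columns (everything
#'   except identifiers and the target).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("timestamp", "date", "count"))
}
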