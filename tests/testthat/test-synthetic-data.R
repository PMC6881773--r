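test_that("rate profile reduces to base/24 under a flat calendar", {
  prof <- build_rate_profile(flat_calendar(75), horizon = 24 * 14)
  expect_equal(prof$rate, rep(75 / 24, 24 * 14))
  prof0 <- build_rate_profile(flat_calendar(0), horizon = 48)
  expect_equal(prof0$rate, rep(0, 48))
})

test_that("default calibration reproduces the holiday/normal rate ratio", {
  prof <- build_rate_profile(calendar_config(), horizon = 5 * 365 * 24)
  ratio <- mean(prof$rate[prof$holiday_flag]) /
    mean(prof$rate[!prof$holiday_flag])
  expect_equal(ratio, 5.45 / 3.31, tolerance = 0.05)
})

test_that("default hourly profile places the stated mass on evening hours", {
  w <- default_hour_weights()
  expect_equal(sum(w[18:24]), 0.60, tolerance = 1e-10)  # hours 17-23
  expect_true(all(which(w == max(w)) %in% 21:23))       # peak 20-22
  expect_true(all(which(w == min(w)) %in% 5:6))         # trough 04-05
  expect_equal(sum(default_weekday_weights()[6:7]), 0.38 / 1.03,
               tolerance = 1e-10)
})

test_that("invalid generator configurations are rejected", {
  expect_error(calendar_config(hour_weights = c(rep(1, 23), -1)),
               "non-negative")
  expect_error(calendar_config(dispersion = -0.5), "dispersion")
  expect_error(build_rate_profile(calendar_config(), horizon = 0), "horizon")
  expect_error(generate_counts(rep(1, 10), dispersion = -1), "dispersion")
})

test_that("hourly counts match the profile's moments and honor the seed", {
  prof <- build_rate_profile(flat_calendar(75), horizon = 1e5)
  x <- generate_counts(prof, seed = 11)
  se <- sqrt(75 / 24 / 1e5)
  expect_lt(abs(mean(x) - 75 / 24), 3 * se)
  expect_identical(x, generate_counts(prof, seed = 11))
  expect_false(identical(x, generate_counts(prof, seed = 12)))
  expect_equal(generate_counts(rep(0, 100), seed = 1), rep(0L, 100))
  # negative binomial keeps the mean but inflates the variance
  y <- generate_counts(prof, dispersion = 0.5, seed = 11)
  expect_lt(abs(mean(y) - 75 / 24), 4 * sqrt(var(y) / 1e5))
  expect_gt(var(y), var(x))
})

test_that("weather is a seasonal sinusoid with clipped humidity", {
  w0 <- generate_weather(24 * 365, seed = 1, temp_noise_sd = 0,
                         humid_noise_sd = 0)
  w0b <- generate_weather(24 * 365, seed = 99, temp_noise_sd = 0,
                          humid_noise_sd = 0)
  expect_equal(w0$temperature, w0b$temperature)  # noiseless limit is exact
  expect_true(all(w0$hour %% 3 == 0))
  w <- generate_weather(24 * 365 * 2, seed = 3)
  expect_true(all(w$humidity >= 0 & w$humidity <= 100))
  month <- lubridate::month(w$timestamp)
  expect_gt(mean(w$temperature[month %in% 6:8]),
            mean(w$temperature[month %in% c(12, 1, 2)]))
})

test_that("arrival times conserve and localize the hourly counts", {
  expect_length(generate_arrival_times(integer(0)), 0)
  tt <- generate_arrival_times(c(2, 0, 1), seed = 5)
  expect_length(tt, 3)
  expect_true(all(tt[1:2] >= 0 & tt[1:2] < 1))
  expect_true(tt[3] >= 2 && tt[3] < 3)
  expect_error(generate_arrival_times(c(1, -2)), ">= 0")

  counts <- generate_counts(build_rate_profile(calendar_config(), 1e4),
                            seed = 7)
  times <- generate_arrival_times(counts, seed = 8)
  expect_false(is.unsorted(times))
  recount <- tabulate(floor(times) + 1L, nbins = length(counts))
  expect_identical(recount, as.integer(counts))
})

test_that("a five-year synthetic trace recovers the configured calendar", {
  cfg <- calendar_config()
  horizon <- 5 * 365 * 24
  prof <- build_rate_profile(cfg, horizon)
  obs <- generate_observations(cfg, horizon, seed = 21)
  expect_identical(obs, generate_observations(cfg, horizon, seed = 21))

  total <- sum(obs$count)
  # weekend share against the profile-implied share, within Monte-Carlo error
  p_wk <- sum(prof$rate[prof$weekend_flag]) / sum(prof$rate)
  emp_wk <- sum(obs$count[obs$weekend_flag]) / total
  expect_lt(abs(emp_wk - p_wk), 3 * sqrt(p_wk * (1 - p_wk) / total))

  # holiday/normal hourly-rate ratio
  hol <- mean(obs$count[obs$holiday_flag])
  nor <- mean(obs$count[!obs$holiday_flag])
  lam_h <- mean(prof$rate[prof$holiday_flag])
  n_h <- sum(prof$holiday_flag)
  expect_lt(abs(hol - lam_h), 3 * sqrt(lam_h / n_h))
  expect_equal(hol / nor, cfg$holiday_multiplier, tolerance = 0.1)

  # fall sits below winter by the configured factor
  fall <- mean(obs$count[obs$season == "fall" & !obs$holiday_flag])
  winter <- mean(obs$count[obs$season == "winter" & !obs$holiday_flag])
  expect_equal(fall / winter, 0.87, tolerance = 0.05)
})
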