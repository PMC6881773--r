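#' Welch moving average
#'
#' Smooths a performance series the way the Welch warm-up procedure
#' prescribes: interior point `i` becomes the mean of points `i-w .. i+w`;
#' head points `i <= w` become the mean of the first `2i - 1` points (the
#' standard symmetric edge rule); the last `w` points are dropped, so the
#' output is `w` points shorter than the input.
#'
#' @param x Numeric series (length > 2w).
#' @param w Half-window in observation points (>= 0); `w = 0` returns `x`.
#' @return Numeric vector of length `length(x) - w`.
#' @examples
#' welch_moving_average(c(5, 9, 7, 7), w = 1) # 5, 7, 23/3
#' @export
welch_moving_average <- function(x, w) {
  if (w < 0 || w != floor(w)) abort("`w` must be a non-negative integer.")
  n <- length(x)
  if (w == 0) return(x)
  if (n <= 2 * w) abort("series must be longer than 2w.")
  cs <- c(0, cumsum(x))
  out <- numeric(n - w)
  head_i <- seq_len(w)
  out[head_i] <- cs[2 * head_i] / (2 * head_i - 1)
  int_i <- (w + 1):(n - w)
  out[int_i] <- (cs[int_i + w + 1] - cs[int_i - w]) / (2 * w + 1)
  out
}

#' Detect the warm-up period with the Welch procedure
#'
#' Averages the hourly performance series (mean LOS per hour) across
#' replications, smooths the average with the Welch moving window, and
#' declares warm-up over at the first hour after which the smoothed series
#' stays inside a tolerance band around its long-run mean for the remainder.
#' This operationalizes the visual judgment of the classical procedure as
#' an explicit band criterion.
#'
#' For an hourly series the window parameter counts *days*: `w = 1` smooths
#' over the past day and the following day (half-window 24 hours), which
#' removes the daily arrival cycle from the curve so the band criterion sees
#' the start-up trend rather than the recurrent within-day swing. Use
#' `w_units = "points"` for series without a daily structure.
#'
#' The long-run mean is estimated from the second half of the smoothed
#' series; hours without patients are linearly interpolated before
#' averaging.
#'
#' @param series Matrix (hours x replications), data frame, or list of
#'   equal-length numeric vectors of per-hour performance values; at least 2
#'   replications.
#' @param w Welch window: days (default) or points, see `w_units`.
#' @param tolerance Band half-width as a fraction of the long-run mean
#'   (default 0.05).
#' @param w_units `"days"` (half-window `24 w` points) or `"points"`.
#' @return Object of class `welch_result`: `warmup` (hours; 0 for a series
#'   stationary from the start), `settled` (FALSE if the band is never held,
#'   in which case `warmup` is the series length), `smoothed` tibble,
#'   `long_run_mean`, `tolerance`, `window_points`.
#' @export
detect_warmup <- function(series, w = 1, tolerance = 0.05,
                          w_units = c("days", "points")) {
  w_units <- match.arg(w_units)
  m <- if (is.list(series) && !is.data.frame(series)) {
    stopifnot(length(unique(lengths(series))) == 1)
    do.call(cbind, series)
  } else {
    as.matrix(series)
  }
  if (ncol(m) < 2) abort("need at least 2 replications.")
  avg <- rowMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  if (anyNA(avg)) {
    idx <- seq_along(avg)
    avg <- stats::approx(idx[!is.na(avg)], avg[!is.na(avg)], xout = idx,
                         rule = 2)$y
  }
  wp <- if (w_units == "days") as.integer(24 * w) else as.integer(w)
  smoothed <- welch_moving_average(avg, wp)
  n <- length(smoothed)
  long_run <- mean(smoothed[ceiling(n / 2):n])
  dev <- abs(smoothed - long_run)
  inside <- dev <= tolerance * abs(long_run)
  # first index from which every later point stays inside the band; the
  # settled stretch must cover at least the final quarter of the series so a
  # lucky last point or two cannot masquerade as a steady state
  ok_from <- rev(cumprod(rev(inside))) > 0
  first <- if (any(ok_from)) which(ok_from)[1] else NA_integer_
  settled <- !is.na(first) && first <= ceiling(0.75 * n)
  structure(
    list(
      warmup = if (settled) first - 1L else length(avg),
      settled = settled,
      smoothed = tibble(hour = seq_len(n), value = smoothed),
      long_run_mean = long_run,
      tolerance = tolerance,
      window_points = wp
    ),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  if (x$settled) {
    cat("<welch_result> warm-up", x$warmup, "h",
        sprintf("(long-run mean %.1f, band +/-%.0f%%)\n",
                x$long_run_mean, 100 * x$tolerance))
  } else {
    cat("<welch_result> no steady state detected within", x$warmup, "h\n")
  }
  invisible(x)
}

#' @describeIn detect_warmup Smoothed series as a tibble.
#' @param x A `welch_result`.
#' @param ... Unused.
#' @method tidy welch_result
#' @export
tidy.welch_result <- function(x, ...) {
  x$smoothed
}

#' Sequential procedure for the number of replications
#'
#' Adds replications one at a time until the relative confidence-interval
#' half-width meets the precision target: with `n` observations, sample mean
#' \eqn{\bar X_n} and variance \eqn{s^2(n)}, the half-width is
#' \eqn{\delta(n, \alpha) = t_{n-1, 1-\alpha/2}\sqrt{s^2(n)/n}}; the
#' procedure stops as soon as \eqn{\delta/\bar X_n \le \gamma'}, returning
#' \eqn{(\bar X_n - \delta,\ \bar X_n + \delta)} as the
#' \eqn{100(1-\alpha)\%} interval.
#'
#' @param run_function Function of the replication index returning one
#'   scalar performance observation (e.g. a replication's mean LOS).
#' @param n0 Starting replication count (>= 2).
#' @param alpha Significance level of the interval (0 < alpha < 1).
#' @param gamma_prime Relative-precision target (0 < gamma' < 1).
#' @param max_n Hard stop; reaching it without convergence is flagged.
#' @return Object of class `replication_plan`: `n`, `sample_mean`,
#'   `sample_variance`, `t_value`, `half_width`, `relative_half_width`,
#'   `ci` (length-2), `converged`, `observations`.
#' @examples
#' obs <- c(10, 12, 11)
#' plan <- sequential_replications(function(i) obs[i], n0 = 3,
#'                                 gamma_prime = 0.23)
#' plan$half_width # ~2.484
#' @export
sequential_replications <- function(run_function, n0 = 2, alpha = 0.05,
                                    gamma_prime = 0.10, max_n = 100) {
  if (n0 < 2) abort("`n0` must be >= 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (gamma_prime <= 0 || gamma_prime >= 1) abort("`gamma_prime` must be in (0, 1).")
  obs <- vapply(seq_len(n0), function(i) as.numeric(run_function(i)),
                numeric(1))
  repeat {
    n <- length(obs)
    xbar <- mean(obs)
    if (xbar == 0) abort("sample mean is zero; relative precision undefined.")
    s2 <- stats::var(obs)
    tv <- qt(1 - alpha / 2, df = n - 1)
    delta <- tv * sqrt(s2 / n)
    rel <- delta / abs(xbar)
    if (rel <= gamma_prime || n >= max_n) {
      return(structure(
        list(n = n, sample_mean = xbar, sample_variance = s2,
             alpha = alpha, t_value = tv, half_width = delta,
             relative_half_width = rel, precision_target = gamma_prime,
             ci = c(xbar - delta, xbar + delta),
             converged = rel <= gamma_prime,
             observations = obs),
        class = "replication_plan"
      ))
    }
    obs <- c(obs, as.numeric(run_function(n + 1L)))
  }
}

#' @export
print.replication_plan <- function(x, ...) {
  cat("<replication_plan>", x$n, "replication(s);",
      sprintf("mean %.3f, CI [%.3f, %.3f], delta/mean %.4f (target %.2f)%s\n",
              x$sample_mean, x$ci[1], x$ci[2], x$relative_half_width,
              x$precision_target,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @describeIn sequential_replications One-row summary tibble.
#' @param x A `replication_plan`.
#' @param ... Unused.
#' @method glance replication_plan
#' @export
glance.replication_plan <- function(x, ...) {
  tibble(n = x$n, sample_mean = x$sample_mean,
         sample_variance = x$sample_variance, t_value = x$t_value,
         half_width = x$half_width,
         relative_half_width = x$relative_half_width,
         ci_low = x$ci[1], ci_high = x$ci[2], converged = x$converged)
}

#' Sweep the stabilization-bed capacity
#'
#' Runs the ED model at every bed count in `beds`, each with the same set of
#' replications. All scenarios of a replication share one arrival trace and
#' one set of patient-level service/routing draws (common random numbers),
#' so differences between bed counts reflect capacity alone. Each
#' replication covers `warm_up + hours` simulated hours; statistics discard
#' the warm-up.
#'
#' @param config An [ed_config()]; its `beds` entry is ignored in favour of
#'   the sweep range.
#' @param beds Integer vector of bed counts (default 7:14).
#' @param replications Replications per bed count.
#' @param hours Post-warm-up hours per replication.
#' @param warm_up Warm-up hours.
#' @param seed Master seed; replication seeds derive from it.
#' @param start_date First date of the arrival trace.
#' @return Tibble of class `ed_sweep`: per bed count the across-replication
#'   mean LOS and bed-queue statistics with 95% t-interval half-widths; the
#'   per-replication table rides in attribute `"replications"`.
#' @examples
#' \donttest{
#' cfg <- ed_config(warm_up = 24, run_length = 500)
#' sw <- bed_sweep(cfg, beds = 7:9, replications = 2, seed = 1)
#' find_optimum_beds(sw)
#' }
#' @export
bed_sweep <- function(config, beds = 7:14,
                      replications = config$replications,
                      hours = config$run_length,
                      warm_up = config$warm_up,
                      seed = config$seed,
                      start_date = "2017-01-01") {
  if (length(beds) == 0) abort("`beds` must be non-empty.")
  if (replications < 2) abort("need at least 2 replications.")
  beds <- sort(unique(as.integer(beds)))
  cfg <- config
  cfg$warm_up <- warm_up
  cfg$run_length <- hours
  horizon <- as.integer(ceiling(warm_up + hours))
  seeds <- matrix(derive_seeds(seed, 3L * replications), ncol = 3L)

  per_rep <- purrr::map(seq_len(replications), function(r) {
    profile <- build_rate_profile(cfg$arrivals, horizon, start_date)
    counts <- generate_counts(profile, dispersion = cfg$arrivals$dispersion,
                              seed = seeds[r, 1])
    arr <- generate_arrival_times(counts, seed = seeds[r, 2])
    purrr::map(beds, function(b) {
      cfg_b <- cfg
      cfg_b$beds <- b
      rep_out <- run_replication(cfg_b, arr, seed = seeds[r, 3],
                                 record_queue = FALSE)
      collect_stats(rep_out) %>%
        mutate(beds = b, replication = r, .before = 1)
    }) %>% purrr::list_rbind()
  }) %>% purrr::list_rbind()

  ci_half <- function(x) {
    if (length(x) < 2 || sd(x) == 0) return(0)
    qt(0.975, df = length(x) - 1) * sd(x) / sqrt(length(x))
  }
  out <- per_rep %>%
    group_by(.data$beds) %>%
    summarise(
      n_reps = dplyr::n(),
      los_ci = ci_half(.data$mean_los),
      mean_los = mean(.data$mean_los),
      mean_bed_wait = mean(.data$mean_bed_wait),
      queue_ci = ci_half(.data$mean_bed_queue),
      mean_bed_queue = mean(.data$mean_bed_queue),
      max_bed_queue = max(.data$max_bed_queue),
      bed_utilization = mean(.data$bed_utilization),
      .groups = "drop"
    ) %>%
    select("beds", "n_reps", "mean_los", "los_ci", "mean_bed_wait",
           "mean_bed_queue", "queue_ci", "max_bed_queue",
           "bed_utilization") %>%
    arrange(.data$beds)
  structure(out, replications = per_rep,
            class = c("ed_sweep", class(tibble())))
}

#' Smallest bed count beyond which extra beds stop paying off
#'
#' Applies a marginal-improvement rule to a bed sweep: the optimum is the
#' smallest bed count `b` such that moving to `b + 1` improves the mean LOS
#' by less than `improvement_threshold` (relative; default 1%). If the curve
#' keeps improving through the last bed count, the largest count is returned
#' with attribute `saturated = FALSE` and a warning.
#'
#' @param sweep An [bed_sweep()] table (sorted by beds ascending).
#' @param improvement_threshold Relative LOS improvement below which an
#'   extra bed no longer counts (default 0.01).
#' @return Integer bed count with attribute `saturated`.
#' @examples
#' tbl <- tibble::tibble(beds = 7:11,
#'                       mean_los = c(100, 80, 70, 69.5, 69.4))
#' find_optimum_beds(tbl) # 9
#' @export
find_optimum_beds <- function(sweep, improvement_threshold = 0.01) {
  tbl <- as_tibble(sweep) %>% arrange(.data$beds)
  if (nrow(tbl) < 2) {
    return(structure(tbl$beds[1], saturated = TRUE))
  }
  los <- tbl$mean_los
  rel_gain <- (los[-length(los)] - los[-1]) / los[-length(los)]
  idx <- which(rel_gain < improvement_threshold)
  if (length(idx) == 0) {
    warn("LOS still improving at the largest bed count; sweep not saturated.")
    return(structure(tbl$beds[nrow(tbl)], saturated = FALSE))
  }
  structure(tbl$beds[idx[1]], saturated = TRUE)
}

#' Hourly-LOS replications of the default model for warm-up analysis
#'
#' Runs `replications` independent replications of the configured ED model
#' from an empty state and returns the per-hour mean-LOS matrix that
#' [detect_warmup()] consumes.
#'
#' @param config An [ed_config()].
#' @param hours Simulated hours per replication (default 300).
#' @param replications Number of replications (>= 2).
#' @param seed Master seed.
#' @param start_date First date of the arrival trace.
#' @return Numeric matrix, `hours` rows x `replications` columns.
#' @export
warmup_replications <- function(config, hours = 300,
                                replications = 5,
                                seed = config$seed,
                                start_date = "2017-01-01") {
  cfg <- config
  cfg$warm_up <- 0
  cfg$run_length <- hours
  seeds <- matrix(derive_seeds(seed, 3L * replications), ncol = 3L)
  cols <- purrr::map(seq_len(replications), function(r) {
    profile <- build_rate_profile(cfg$arrivals, as.integer(hours), start_date)
    counts <- generate_counts(profile, dispersion = cfg$arrivals$dispersion,
                              seed = seeds[r, 1])
    arr <- generate_arrival_times(counts, seed = seeds[r, 2])
    rep_out <- run_replication(cfg, arr, seed = seeds[r, 3])
    hourly_los(rep_out, hours = hours)
  })
  do.call(cbind, cols)
}
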