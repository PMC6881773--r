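#' Plot methods
#'
#' `autoplot()` methods render each result type the way its consumers expect
#' to see it: the rate profile as an hourly intensity curve, a bed sweep as
#' LOS and queue-length curves against bed count, a Welch result as the
#' smoothed series with its tolerance band and detected cut, and a CV report
#' as per-fold metric points.
#'
#' @param object The object to plot.
#' @param days How many leading days of the rate profile to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @name edsim-autoplot
NULL

#' @rdname edsim-autoplot
#' @method autoplot rate_profile
#' @export
autoplot.rate_profile <- function(object, days = 7, ...) {
  df <- as_tibble(object) %>% head(24 * days)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$rate)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = NULL, y = "expected arrivals / hour",
                  title = "Nonhomogeneous arrival-rate profile") +
    ggplot2::theme_minimal()
}

#' @rdname edsim-autoplot
#' @method autoplot ed_sweep
#' @export
autoplot.ed_sweep <- function(object, ...) {
  # assemble the two metric/ci pairs by hand; clearer than a pivot pattern
  df <- dplyr::bind_rows(
    tibble(beds = object$beds, metric = "mean LOS (min)",
           value = object$mean_los, ci = object$los_ci),
    tibble(beds = object$beds, metric = "mean bed queue",
           value = object$mean_bed_queue, ci = object$queue_ci)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beds, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$ci,
                                          ymax = .data$value + .data$ci),
                             size = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "stabilization beds", y = NULL,
                  title = "Bed-capacity sweep") +
    ggplot2::theme_minimal()
}

#' @rdname edsim-autoplot
#' @method autoplot welch_result
#' @export
autoplot.welch_result <- function(object, ...) {
  band <- object$tolerance * abs(object$long_run_mean)
  ggplot2::ggplot(object$smoothed,
                  ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$long_run_mean - band,
                      ymax = object$long_run_mean + band,
                      alpha = 0.15, fill = "forestgreen") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = object$long_run_mean,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$warmup, color = "firebrick") +
    ggplot2::labs(x = "hour", y = "smoothed mean LOS (min)",
                  title = sprintf("Welch warm-up detection: %s h",
                                  if (object$settled) object$warmup
                                  else "not settled")) +
    ggplot2::theme_minimal()
}

#' @rdname edsim-autoplot
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy(object) %>%
    filter(!.data$failed) %>%
    tidyr::pivot_longer(c("mape", "mae"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Cross-validated forecast error:",
                                object$model)) +
    ggplot2::theme_minimal()
}

#' @rdname edsim-autoplot
#' @method autoplot subset_ranking
#' @export
autoplot.subset_ranking <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$cv_loss)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6,
                         color = "steelblue") +
    ggplot2::labs(x = "subset size", y = paste("CV", attr(object, "loss")),
                  title = "Exhaustive wrapper feature selection") +
    ggplot2::theme_minimal()
}

#' @describeIn bed_sweep Per-replication sweep rows.
#' @param x An `ed_sweep`.
#' @param ... Unused.
#' @method tidy ed_sweep
#' @export
tidy.ed_sweep <- function(x, ...) {
  attr(x, "replications")
}

#' @describeIn bed_sweep One-row summary with the 1%-rule optimum.
#' @method glance ed_sweep
#' @export
glance.ed_sweep <- function(x, ...) {
  opt <- suppressWarnings(find_optimum_beds(x))
  tibble(
    n_scenarios = nrow(x),
    beds_min = min(x$beds),
    beds_max = max(x$beds),
    optimum_beds = as.integer(opt),
    saturated = attr(opt, "saturated"),
    los_at_optimum = x$mean_los[x$beds == as.integer(opt)]
  )
}
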