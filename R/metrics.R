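#' Mean absolute percentage error
#'
#' \deqn{MAPE = \frac{100}{n'} \sum_{x_i \ne 0} \frac{|x_i - p_i|}{x_i}}
#' Hours with a zero actual are excluded from the sum (the ratio is undefined
#' there, and night hours of an hourly arrival series are frequently zero);
#' `n'` counts only the retained rows.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return MAPE in percent (a single number, >= 0).
#' @examples
#' mape(c(2, 4), c(1, 5)) # 37.5
#' @export
mape <- function(actual, predicted) {
  check_paired(actual, predicted)
  keep <- actual != 0
  if (!any(keep)) {
    abort("MAPE is undefined: all actual values are zero.")
  }
  100 * mean(abs(actual[keep] - predicted[keep]) / actual[keep])
}

#' Mean absolute error
#'
#' \deqn{MAE = \frac{1}{n} \sum |x_i - p_i|} in the units of the series
#' (arrivals/hour for hourly forecasts).
#'
#' @inheritParams mape
#' @return MAE (a single number, >= 0).
#' @examples
#' mae(c(2, 4), c(1, 5)) # 1
#' @export
mae <- function(actual, predicted) {
  check_paired(actual, predicted)
  mean(abs(actual - predicted))
}

check_paired <- function(actual, predicted) {
  if (length(actual) == 0) abort("empty input series.")
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.")
  }
  if (anyNA(actual) || anyNA(predicted)) abort("series contain NA.")
  invisible(TRUE)
}

#' Forecast metrics for a pair of series
#'
#' @inheritParams mape
#' @return One-row tibble with `mape` (%) and `mae` (arrivals/hour).
#' @export
forecast_metrics <- function(actual, predicted) {
  tibble(mape = mape(actual, predicted), mae = mae(actual, predicted))
}
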