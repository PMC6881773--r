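#' k-fold cross-validated forecast evaluation
#'
#' Shuffles the rows under a fixed seed, splits them into `k` folds, and for
#' each fold fits the model on the remaining rows and scores the held-out
#' predictions with MAPE and MAE. Predictions are clipped at zero before
#' scoring. A fold whose fit or prediction fails is marked failed and carries
#' NA metrics; the report flags it rather than aborting the whole experiment.
#'
#' @param model A [forecast_model()].
#' @param table An `ed_features` table (or any data frame containing the
#'   predictor columns plus the response).
#' @param k Number of folds (default 10, >= 2).
#' @param seed Integer seed for the fold shuffle.
#' @param response Name of the target column.
#' @param features Predictor columns handed to the model; default all feature
#'   columns of the table.
#' @return Object of class `cv_report`: list with `folds` (per-fold tibble:
#'   `fold`, `n_test`, `mape`, `mae`, `failed`) and `summary` (mean/sd/min/max
#'   of each metric over the successful folds), plus the model name.
#' @examples
#' obs <- generate_observations(horizon = 24 * 30, seed = 3)
#' tab <- build_feature_table(obs)
#' kfold_evaluate(model_mean_rate(), tab, k = 5, seed = 1)
#' @export
kfold_evaluate <- function(model, table, k = 10, seed = 1L,
                           response = "count", features = NULL) {
  stopifnot(inherits(model, "forecast_model"))
  n <- nrow(table)
  if (k < 2) abort("`k` must be >= 2.")
  if (n < k) abort("need at least `k` rows.")
  features <- features %||% feature_columns(table)
  data <- as_tibble(table)[c(features, response)]

  fold_id <- with_local_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })

  folds <- purrr::map(seq_len(k), function(f) {
    test_idx <- which(fold_id == f)
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    res <- tryCatch({
      state <- model$fit(train, response)
      pred <- pmax(0, model$predict(state, test))
      stopifnot(all(is.finite(pred)))
      tibble(fold = f, n_test = length(test_idx),
             mape = mape(test[[response]], pred),
             mae = mae(test[[response]], pred),
             failed = FALSE)
    }, error = function(e) {
      tibble(fold = f, n_test = length(test_idx),
             mape = NA_real_, mae = NA_real_, failed = TRUE)
    })
    res
  }) %>% purrr::list_rbind()

  ok <- folds %>% filter(!.data$failed)
  if (nrow(ok) == 0) abort("every fold failed to fit.")
  summ <- ok %>%
    tidyr::pivot_longer(c("mape", "mae"), names_to = "metric") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              min = min(.data$value), max = max(.data$value),
              .groups = "drop")

  structure(
    list(model = model$name, k = k, seed = seed,
         folds = folds, summary = summ,
         any_failed = any(folds$failed)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$model, "-", x$k, "folds\n")
  print(x$summary)
  if (x$any_failed) cat("note: some folds failed to fit\n")
  invisible(x)
}

#' @describeIn kfold_evaluate Per-fold metrics as a tibble.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  x$folds
}

#' @describeIn kfold_evaluate One-row summary (mean/sd/min/max MAPE and MAE).
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  wide <- tidyr::pivot_wider(s, names_from = "metric",
                             values_from = c("mean", "sd", "min", "max"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(tibble(model = x$model, folds = x$k), wide)
}
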