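#' Pairwise Pearson correlation matrix of a feature table
#'
#' Computes all pairwise Pearson correlations between the (numerically
#' encoded) feature columns and the target. A zero-variance column cannot be
#' correlated with anything; its entries are reported as 0 with a warning
#' rather than NA so the matrix stays usable downstream.
#'
#' @param table A data frame; logical columns are coerced to 0/1, all columns
#'   must be numeric after coercion.
#' @param columns Columns to include (default: every column except
#'   identifiers).
#' @return Symmetric numeric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
correlation_matrix <- function(table, columns = NULL) {
  tab <- as_tibble(table)
  columns <- columns %||% setdiff(names(tab), c("timestamp", "date"))
  x <- tab[columns]
  x <- data.frame(lapply(x, function(v) as.numeric(v)))
  if (nrow(x) < 2) abort("need at least 2 rows.")
  zero_var <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  m <- suppressWarnings(cor(x))
  if (any(zero_var)) {
    warn(paste("zero-variance column(s) reported as correlation 0:",
               paste(columns[zero_var], collapse = ", ")))
    m[zero_var, ] <- 0
    m[, zero_var] <- 0
  }
  diag(m) <- 1
  dimnames(m) <- list(columns, columns)
  m
}

#' Exhaustive wrapper feature selection
#'
#' Evaluates every non-empty subset of the candidate features by
#' cross-validated loss under a supplied learner and returns the full ranking
#' together with the best subset. The loss is the mean absolute error across
#' folds (MAPE is available as an alternative). Ties are broken toward the
#' smaller subset, then lexicographically, so the selection is invariant to
#' the order in which candidates are listed.
#'
#' With `k` candidates the wrapper fits `folds * (2^k - 1)` models; a guard
#' rejects `k > max_features` (default 20) with a pointer toward heuristic
#' selectors.
#'
#' @param table Feature table (data frame) holding candidates plus response.
#' @param features Character vector of candidate feature columns.
#' @param estimator A [forecast_model()]; defaults to a fixed-seed random
#'   forest, the classic workhorse behind wrapper selection.
#' @param loss `"mae"` (default) or `"mape"`.
#' @param folds Folds of the inner cross-validation (default 5).
#' @param seed Integer seed shared by the fold shuffle of all subsets.
#' @param response Target column name.
#' @param max_features Combinatorial guard (default 20).
#' @return Object of class `subset_ranking`: a tibble with one row per subset
#'   (`features` list-column, `subset`, `size`, `cv_loss`, `rank`), with the
#'   winning subset in attribute `best` and accessor [best_subset()].
#' @examples
#' \donttest{
#' obs <- generate_observations(horizon = 24 * 60, seed = 5)
#' tab <- build_feature_table(obs)
#' sel <- exhaustive_select(tab, c("hour_of_day", "weekend_flag", "season"),
#'                          estimator = model_lm(), folds = 3, seed = 1)
#' best_subset(sel)
#' }
#' @export
exhaustive_select <- function(table, features = NULL,
                              estimator = model_rf(),
                              loss = c("mae", "mape"),
                              folds = 5, seed = 1L,
                              response = "count",
                              max_features = 20) {
  loss <- match.arg(loss)
  features <- sort(features %||% feature_columns(table))
  k <- length(features)
  if (k < 1) abort("need at least one candidate feature.")
  if (k > max_features) {
    abort(sprintf(paste(
      "%d candidate features would require %s subset evaluations;",
      "use a heuristic selector instead of the exhaustive wrapper."),
      k, format(2^k - 1, big.mark = ",")))
  }
  data <- as_tibble(table)

  subsets <- purrr::map(seq_len(2^k - 1), function(mask) {
    features[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
  })

  cv_loss <- vapply(subsets, function(fs) {
    rep_metric <- kfold_evaluate(estimator, data, k = folds, seed = seed,
                                 response = response, features = fs)
    mean(tidy(rep_metric)[[loss]], na.rm = TRUE)
  }, numeric(1))

  ranking <- tibble(
    features = subsets,
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets),
    cv_loss = cv_loss
  ) %>%
    arrange(.data$cv_loss, .data$size, .data$subset) %>%
    mutate(rank = row_number())

  structure(ranking,
            best = ranking$features[[1]],
            loss = loss,
            class = c("subset_ranking", class(tibble())))
}

#' Winning subset of an exhaustive selection
#'
#' @param ranking A `subset_ranking` from [exhaustive_select()].
#' @return Character vector of the minimum-loss feature subset.
#' @export
best_subset <- function(ranking) {
  attr(ranking, "best")
}
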