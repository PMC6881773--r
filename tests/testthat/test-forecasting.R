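test_that("MAPE and MAE match hand computations and edge rules", {
  expect_equal(mape(c(2, 4), c(1, 5)), 37.5)
  expect_equal(mae(c(2, 4), c(1, 5)), 1)
  expect_equal(mape(c(3, 7, 2), c(3, 7, 2)), 0)
  expect_equal(mae(c(3, 7, 2), c(3, 7, 2)), 0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3) + 2.5), 2.5)  # constant offset
  # zero-actual rows are excluded from MAPE, not from MAE
  expect_equal(mape(c(0, 2), c(7, 2)), 0)
  expect_equal(mae(c(0, 2), c(7, 2)), 3.5)
  expect_error(mape(c(0, 0), c(1, 2)), "zero")
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("MAE is symmetric while MAPE is not", {
  a <- c(2, 5, 9)
  p <- c(3, 4, 11)
  expect_equal(mae(a, p), mae(p, a))
  expect_false(isTRUE(all.equal(mape(a, p), mape(p, a))))
})

test_that("baseline predictors behave as documented", {
  obs <- tiny_observations(24 * 30, seed = 2)
  tab <- build_feature_table(obs)
  mr <- model_mean_rate()
  pred <- mr$predict(mr$fit(tab, "count"), tab)
  expect_equal(pred, tab$mean_arrival_rate)
  expect_equal(pred[1], 0)  # cold start

  # Poisson baseline: seed-reproducible, zero rate -> zero prediction
  po <- model_poisson(seed = 4)
  st <- po$fit(tab, "count")
  p1 <- po$predict(st, tab)
  expect_identical(p1, po$predict(st, tab))
  zero <- tab
  zero$count <- 0L
  st0 <- po$fit(zero, "count")
  expect_true(all(po$predict(st0, zero) == 0))
})

test_that("slot means converge and the mean-rate baseline beats Poisson draws", {
  # stationary Poisson data: the running slot mean approaches the true rate
  cfg <- flat_calendar(75)
  obs <- generate_observations(cfg, horizon = 10000, seed = 31)
  tab <- build_feature_table(obs)
  late <- tab$mean_arrival_rate[tab$timestamp >
                                  tab$timestamp[nrow(tab) - 24 * 14]]
  expect_lt(max(abs(late - 75 / 24)), 0.5)

  # extra sampling variance makes the Poisson-draw comparator worse in MAPE
  worse <- vapply(1:10, function(s) {
    po <- model_poisson(seed = s)
    p_draw <- po$predict(po$fit(tab, "count"), tab)
    keep <- tab$mean_arrival_rate > 0
    mape(tab$count[keep], p_draw[keep]) -
      mape(tab$count[keep], tab$mean_arrival_rate[keep])
  }, numeric(1))
  expect_gt(mean(worse), 0)
  expect_gt(mean(worse > 0), 0.8)
})

test_that("k-fold harness reports fold metrics, handles failures, is seeded", {
  obs <- tiny_observations(24 * 20, seed = 6)
  tab <- build_feature_table(obs)

  # training-mean memorizer on constant data scores 0 in every fold
  memorizer <- forecast_model(
    "mean", fit = function(data, response) mean(data[[response]]),
    predict = function(state, newdata) rep(state, nrow(newdata)))
  const <- tab
  const$count <- 4L
  rep0 <- kfold_evaluate(memorizer, const, k = 5, seed = 1)
  expect_equal(tidy(rep0)$mape, rep(0, 5))
  expect_equal(glance(rep0)$mape_mean, 0)

  # leave-one-out boundary runs
  small <- const[1:20, ]
  loo <- kfold_evaluate(memorizer, small, k = 20, seed = 1)
  expect_equal(nrow(tidy(loo)), 20)

  # summary equals the hand average of fold values
  cv <- kfold_evaluate(model_mean_rate(), tab, k = 10, seed = 3)
  expect_equal(glance(cv)$mae_mean, mean(tidy(cv)$mae))
  expect_equal(glance(cv)$mape_min, min(tidy(cv)$mape))
  # same seed -> identical report; fold count as configured
  cv2 <- kfold_evaluate(model_mean_rate(), tab, k = 10, seed = 3)
  expect_identical(tidy(cv), tidy(cv2))
  expect_equal(nrow(tidy(cv)), 10)

  # predictions are clipped at zero before scoring
  negative <- forecast_model(
    "neg", fit = function(data, response) NULL,
    predict = function(state, newdata) rep(-5, nrow(newdata)))
  repn <- kfold_evaluate(negative, const, k = 4, seed = 1)
  expect_equal(glance(repn)$mae_mean, 4)  # |4 - 0|, not |4 - (-5)|

  # a failing model is flagged, not fatal
  flaky <- forecast_model(
    "flaky",
    fit = function(data, response) {
      if (stats::runif(1) < 2) stop("no fit") else NULL
    },
    predict = function(state, newdata) rep(0, nrow(newdata)))
  expect_error(kfold_evaluate(flaky, const, k = 4, seed = 1), "every fold")
})

test_that("sequence-model utilities: scaling and ordered split", {
  x <- c(3, 9, 6)
  expect_equal(minmax_scale(x), c(0, 1, 0.5))
  expect_equal(minmax_scale(rep(2, 4)), rep(0, 4))
  expect_equal(minmax_scale(5, from = c(0, 10)), 0.5)

  df <- tibble::tibble(i = 1:1000)
  sp <- train_validation_split(df, 0.8)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$validation), 200)
  expect_equal(sp$train$i, 1:800)          # order preserving
  expect_equal(sp$validation$i, 801:1000)
})

test_that("the recurrent adapter stores its configuration and degrades", {
  m <- model_lstm()
  hp <- attr(m, "hyperparameters")
  expect_equal(hp$hidden_units, 300)
  expect_equal(hp$learning_rate, 5e-4)
  expect_equal(hp$train_frac, 0.8)
  expect_true(hp$stateful)

  obs <- tiny_observations(24 * 5)
  tab <- build_feature_table(obs)
  expect_warning(st <- m$fit(tab, "count"), "mean-rate")
  expect_equal(m$predict(st, tab), tab$mean_arrival_rate)
  # statefulness requires a contiguous hourly sequence
  expect_error(suppressWarnings(m$fit(tab[-5, ], "count")), "gap")
})
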