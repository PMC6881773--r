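test_that("Welch moving average matches hand-computed windows", {
  expect_equal(welch_moving_average(c(5, 9, 7, 7), w = 1),
               c(5, 7, 23 / 3))
  x <- c(2, 4, 6, 8, 10)
  expect_equal(welch_moving_average(x, w = 0), x)
  expect_equal(welch_moving_average(rep(3, 50), w = 5), rep(3, 45))
  expect_length(welch_moving_average(x, w = 2), 3)
  expect_error(welch_moving_average(x, w = -1), "non-negative")
  expect_error(welch_moving_average(x, w = 3), "longer")
})

test_that("warm-up detection: stationary series settle at zero", {
  m <- matrix(10, nrow = 200, ncol = 3)
  res <- detect_warmup(m, w = 2, w_units = "points")
  expect_equal(res$warmup, 0)
  expect_true(res$settled)
})

test_that("warm-up detection brackets a planted exponential transient", {
  tau <- 10
  level <- 100
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    t <- 1:300
    reps <- replicate(5, level * (1 - exp(-t / tau)) + rnorm(300, 0, 1))
    detect_warmup(reps, w = 8, tolerance = 0.05,
                  w_units = "points")$warmup
  }, numeric(1))
  # detected warm-up within [2 tau, 5 tau] for every seed
  expect_true(all(hits >= 2 * tau & hits <= 5 * tau))
})

test_that("warm-up detection ignores added post-settlement hours", {
  set.seed(5)
  t <- 1:200
  base <- replicate(4, 50 * (1 - exp(-t / 8)) + rnorm(200, 0, 0.4))
  ext <- rbind(base, replicate(4, 50 + rnorm(150, 0, 0.4)))
  w1 <- detect_warmup(base, w = 6, w_units = "points")
  w2 <- detect_warmup(ext, w = 6, w_units = "points")
  expect_true(w1$settled && w2$settled)
  expect_lt(abs(w1$warmup - w2$warmup), 6)
})

test_that("a series that never settles is flagged", {
  t <- 1:240
  osc <- replicate(3, 10 + 5 * sin(t / 4))
  res <- detect_warmup(osc, w = 1, w_units = "points", tolerance = 0.05)
  expect_false(res$settled)
  expect_equal(res$warmup, 240)
})

test_that("sequential replication sizing reproduces the hand example", {
  obs <- c(10, 12, 11, 11, 11)
  plan <- sequential_replications(function(i) obs[i], n0 = 3, alpha = 0.05,
                                  gamma_prime = 0.23)
  expect_equal(plan$n, 3)
  expect_equal(plan$sample_mean, 11)
  expect_equal(plan$sample_variance, 1)
  expect_equal(plan$t_value, qt(0.975, 2))
  expect_equal(round(plan$half_width, 4), 2.4841)
  expect_equal(plan$relative_half_width, 2.484139 / 11, tolerance = 1e-5)
  expect_equal(plan$ci, 11 + c(-1, 1) * plan$half_width)
  expect_true(plan$converged)

  # with a tighter target the same data demand a fourth replication
  plan2 <- sequential_replications(function(i) obs[i], n0 = 3,
                                   gamma_prime = 0.22)
  expect_gt(plan2$n, 3)
})

test_that("zero-variance runs stop immediately at n0", {
  plan <- sequential_replications(function(i) 42, n0 = 2)
  expect_equal(plan$n, 2)
  expect_equal(plan$half_width, 0)
  expect_true(plan$converged)
  expect_error(sequential_replications(function(i) 0, n0 = 2), "zero")
})

test_that("the procedure stops at the brute-force smallest qualifying n", {
  set.seed(8)
  draws <- 20 + rnorm(60, sd = 4) / sqrt(seq_len(60))  # shrinking variance
  gp <- 0.05
  plan <- sequential_replications(function(i) draws[i], n0 = 2,
                                  gamma_prime = gp, max_n = 60)
  oracle <- NA_integer_
  for (n in 2:60) {
    x <- draws[1:n]
    delta <- qt(0.975, n - 1) * sqrt(var(x) / n)
    if (delta / mean(x) <= gp) { oracle <- n; break }
  }
  expect_equal(plan$n, oracle)
  # hitting max_n without convergence is flagged
  capped <- sequential_replications(function(i) rnorm(1, 1, 50), n0 = 2,
                                    gamma_prime = 0.01, max_n = 5)
  expect_equal(capped$n, 5)
  expect_false(capped$converged)
})

test_that("the 1% marginal-improvement rule picks the documented optimum", {
  tbl <- tibble::tibble(beds = 7:11, mean_los = c(100, 80, 70, 69.5, 69.4))
  expect_equal(as.integer(find_optimum_beds(tbl)), 9)
  flat <- tibble::tibble(beds = 7:10, mean_los = rep(50, 4))
  expect_equal(as.integer(find_optimum_beds(flat)), 7)
  improving <- tibble::tibble(beds = 7:10, mean_los = c(100, 80, 60, 40))
  expect_warning(opt <- find_optimum_beds(improving), "not saturated")
  expect_equal(as.integer(opt), 10)
  expect_false(attr(opt, "saturated"))
})

test_that("small bed sweeps are reproducible and load-monotone", {
  cfg <- ed_config(warm_up = 24, run_length = 400)
  sw <- bed_sweep(cfg, beds = c(7, 10), replications = 2, seed = 3)
  expect_equal(nrow(sw), 2)
  sw2 <- bed_sweep(cfg, beds = c(7, 10), replications = 2, seed = 3)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))  # bit-reproducible
  expect_lte(sw$mean_los[sw$beds == 10], sw$mean_los[sw$beds == 7])

  one <- bed_sweep(cfg, beds = 9, replications = 2, seed = 3)
  expect_equal(nrow(one), 1)

  # doubling the arrival volume raises every mean LOS
  heavy_cfg <- cfg
  heavy_cfg$arrivals <- calendar_config(base_daily_mean = 150)
  heavy <- bed_sweep(heavy_cfg, beds = c(7, 10), replications = 2, seed = 3)
  expect_true(all(heavy$mean_los > sw$mean_los))
})

test_that("warm-up replications feed the detector at matching shape", {
  cfg <- ed_config()
  m <- warmup_replications(cfg, hours = 120, replications = 3, seed = 2)
  expect_equal(dim(m), c(120, 3))
  m2 <- warmup_replications(cfg, hours = 120, replications = 3, seed = 2)
  expect_identical(m, m2)
})
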