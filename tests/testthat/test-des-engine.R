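test_that("events run in time order with insertion-order ties", {
  sim <- sim_new()
  log <- character(0)
  sim_schedule(sim, 5, function(d) log <<- c(log, d), "A")
  sim_schedule(sim, 5, function(d) log <<- c(log, d), "B")
  sim_schedule(sim, 2, function(d) log <<- c(log, d), "C")
  sim_run(sim)
  expect_equal(log, c("C", "A", "B"))
  expect_equal(sim_now(sim), 5)

  # empty event list: run_until returns immediately at the end time
  sim2 <- sim_new()
  sim_run(sim2, until = 10)
  expect_equal(sim_now(sim2), 10)

  expect_error(sim_schedule(sim, 1, function(d) NULL), "past")
})

test_that("a thousand random events execute in sorted order", {
  set.seed(7)
  times <- runif(1000, 0, 100)
  sim <- sim_new()
  seen <- numeric(0)
  for (t in times) sim_schedule(sim, t, function(d) seen <<- c(seen, d), t)
  sim_run(sim)
  expect_equal(seen, sort(times))  # brute-force sort oracle
})

test_that("seize/release implements FIFO waiting with exact hand schedules", {
  # capacity 1: second request waits exactly until the first release
  sim <- sim_new()
  res <- sim_resource(sim, "r", 1)
  waits <- c(a = NA_real_, b = NA_real_)
  sim_schedule(sim, 0, function(d) {
    sim_seize(res, "a", function(d2, w) {
      waits["a"] <<- w
      sim_schedule(sim, sim_now(sim) + 5, function(d3) sim_release(res))
    })
  })
  sim_schedule(sim, 1, function(d) {
    sim_seize(res, "b", function(d2, w) {
      waits["b"] <<- w
      sim_schedule(sim, sim_now(sim) + 5, function(d3) sim_release(res))
    })
  })
  sim_run(sim)
  expect_equal(waits, c(a = 0, b = 4))

  # capacity 2: both go straight in
  sim <- sim_new()
  res2 <- sim_resource(sim, "r", 2)
  w2 <- numeric(0)
  for (t in c(0, 1)) {
    sim_schedule(sim, t, function(d) {
      sim_seize(res2, NULL, function(d2, w) w2 <<- c(w2, w))
    })
  }
  sim_run(sim)
  expect_equal(w2, c(0, 0))

  # arrivals at 0 and 10 with service 5 on one server: nobody waits
  sim <- sim_new()
  res3 <- sim_resource(sim, "r", 1)
  w3 <- numeric(0)
  for (t in c(0, 10)) {
    sim_schedule(sim, t, function(d) {
      sim_seize(res3, NULL, function(d2, w) {
        w3 <<- c(w3, w)
        sim_schedule(sim, sim_now(sim) + 5, function(d3) sim_release(res3))
      })
    })
  }
  sim_run(sim)
  expect_equal(w3, c(0, 0))
})

test_that("release guards: idle release and non-holder release error", {
  sim <- sim_new()
  res <- sim_resource(sim, "r", 1)
  expect_error(sim_release(res), "idle")

  tracked <- sim_resource(sim, "t", 2, track_holders = TRUE)
  sim_seize(tracked, NULL, function(d, w) NULL, entity = "p1")
  expect_error(sim_release(tracked, entity = "p2"), "does not hold")
  expect_silent(sim_release(tracked, entity = "p1"))
})

test_that("distribution samplers match their closed-form moments", {
  set.seed(99)
  u <- sample_duration(dist_unif(2, 4), 1e5)
  expect_true(all(u >= 2 & u <= 4))
  expect_lt(abs(mean(u) - 3), 3 * sqrt((4 - 2)^2 / 12 / 1e5))

  tr <- sample_duration(dist_tria(30, 60, 120), 1e5)
  expect_true(all(tr >= 30 & tr <= 120))
  var_tria <- (30^2 + 60^2 + 120^2 - 30 * 60 - 30 * 120 - 60 * 120) / 18
  expect_lt(abs(mean(tr) - 70), 3 * sqrt(var_tria / 1e5))
  expect_equal(dist_mean(dist_tria(30, 60, 120)), 70)

  expect_equal(sample_duration(dist_tria(5, 5, 5), 10), rep(5, 10))
  expect_equal(sample_duration(dist_const(7), 3), rep(7, 3))
  expect_error(dist_tria(5, 4, 6), "TRIA")
  expect_error(dist_unif(4, 2), "UNIF")
})

test_that("time-average queue statistics equal the brute-force step integral", {
  sim <- sim_new()
  res <- sim_resource(sim, "r", 1, record_queue = TRUE)
  service <- c(4, 4, 4)
  for (t in c(0, 1, 2)) {
    sim_schedule(sim, t, function(d) {
      sim_seize(res, NULL, function(d2, w) {
        sim_schedule(sim, sim_now(sim) + 4, function(d3) sim_release(res))
      })
    })
  }
  sim_run(sim)
  horizon <- sim_now(sim)
  qs <- queue_series(res)
  # step-function integral of the recorded series
  steps <- rbind(qs, tibble::tibble(time = horizon, queue = NA))
  area <- sum(diff(steps$time) * qs$queue)
  stats <- resource_stats(res, until = horizon)
  expect_equal(stats$mean_queue, area / horizon)
  expect_equal(stats$max_queue, 2)
  expect_equal(stats$mean_busy, 12 / horizon)  # 3 services of 4 min
})

test_that("the engine satisfies Little's law on an M/M/1 queue", {
  q <- run_mm1(lambda = 0.5, mu = 1, horizon = 2e5, seed = 12)
  n_done <- length(q$departures)
  W <- mean(q$departures - q$arrivals[seq_len(n_done)])
  lambda_hat <- length(q$arrivals) / q$horizon
  L <- q$stats$mean_busy + q$stats$mean_queue  # time-average in system
  expect_lt(abs(L - lambda_hat * W) / L, 0.05)
  # and the numbers sit near the analytic M/M/1 values (rho = 0.5)
  expect_equal(W, 2, tolerance = 0.1)
  expect_equal(L, 1, tolerance = 0.1)
})
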