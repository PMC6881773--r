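test_that("scenario configuration validates its invariants", {
  expect_error(ed_config(beds = 0), "beds")
  expect_error(ed_config(routing = list(p_lab_after_ed = 1.4)), "routing")
  expect_error(ed_config(routing = list(
    specialty_split = c(pediatrician = 0.5, otorhinolaryngology = 0.2,
                        internal_medicine = 0.1, orthopedics = 0.1,
                        other = 0.2))), "sum to 1")
  expect_error(ed_config(capacities = list(ed_physician = 0)), "capacities")
  cfg <- ed_config()
  expect_equal(sum(cfg$routing$specialty_split), 1)
  expect_equal(cfg$routing$p_lab_after_ed, 0.70)
  expect_equal(cfg$routing$p_attending, 0.50)
  expect_equal(dist_mean(cfg$service$stabilization), 70)
})

test_that("scenario config round-trips through the key-value file", {
  cfg <- ed_config(beds = 9, routing = list(ambulance_fraction = 0.08),
                   warm_up = 12, run_length = 100)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ed_config(cfg, path)
  back <- read_ed_config(path)
  expect_equal(back$beds, 9)
  expect_equal(back$routing$ambulance_fraction, 0.08)
  expect_equal(back$routing$specialty_split, cfg$routing$specialty_split)
  expect_equal(back$service$ed_exam, cfg$service$ed_exam)
  expect_equal(back$warm_up, 12)
})

test_that("uncongested mean LOS matches the closed-form stage-mean sum", {
  # all routing probabilities zero: triage + ED exam + stabilization only,
  # so E[LOS] = 3 + 28/3 + 70 = 82.33 min with no waiting anywhere
  cfg <- uncongested_config(
    routing = list(ambulance_fraction = 0, p_lab_after_ed = 0,
                   p_attending = 0, p_lab_after_attending = 0,
                   p_admission = 0),
    run_length = 3400)
  arr <- constant_trace(3400, per_hour = 3, seed = 2)
  rep1 <- run_replication(cfg, arr, seed = 3)
  n <- nrow(rep1$patients)
  expect_gte(n, 1e4)
  var_stage <- (4 - 2)^2 / 12 +
    (5^2 + 8^2 + 15^2 - 5 * 8 - 5 * 15 - 8 * 15) / 18 +
    (30^2 + 60^2 + 120^2 - 30 * 60 - 30 * 120 - 60 * 120) / 18
  expect_lt(abs(mean(rep1$patients$los) - (3 + 28 / 3 + 70)),
            3 * sqrt(var_stage / n))
  expect_true(all(rep1$patients$wait_bed == 0))
})

test_that("ambulance arrivals skip the triage room", {
  cfg <- uncongested_config(routing = list(ambulance_fraction = 1),
                            run_length = 100)
  rep1 <- run_replication(cfg, constant_trace(100, 3, seed = 1), seed = 2)
  expect_true(all(is.na(rep1$patients$t_triage)))
  expect_true(all(rep1$patients$ambulance))

  cfg0 <- uncongested_config(routing = list(ambulance_fraction = 0),
                             run_length = 100)
  rep0 <- run_replication(cfg0, constant_trace(100, 3, seed = 1), seed = 2)
  expect_false(anyNA(rep0$patients$t_triage))
})

test_that("route timestamps are monotone and every patient departs", {
  cfg <- ed_config(warm_up = 0, run_length = 300)
  arr <- generate_arrival_times(
    generate_counts(build_rate_profile(cfg$arrivals, 300), seed = 4),
    seed = 5)
  rep1 <- run_replication(cfg, arr, seed = 6)
  p <- rep1$patients
  expect_false(anyNA(p$departure))            # conservation: all complete
  expect_true(all(p$los > 0))
  stage_cols <- c("arrival", "t_triage", "t_ed", "t_lab1", "t_att",
                  "t_lab2", "t_stab", "departure")
  mono <- apply(as.matrix(p[stage_cols]), 1,
                function(r) !is.unsorted(r[!is.na(r)]))
  expect_true(all(mono))
  # route consistency: lab timestamps only for patients routed there
  expect_equal(is.na(p$t_lab1), !p$lab_via_ed)
  expect_equal(is.na(p$t_att), !p$referred)
  expect_true(all(is.na(p$t_lab2[!p$referred])))
})

test_that("simulated routing fractions echo the configured probabilities", {
  cfg <- uncongested_config(run_length = 6000)
  arr <- constant_trace(6000, per_hour = 4, seed = 7)
  rep1 <- run_replication(cfg, arr, seed = 8)
  p <- rep1$patients
  n <- nrow(p)
  se <- function(prob) 3 * sqrt(prob * (1 - prob) / n)
  expect_lt(abs(mean(p$lab_via_ed) - 0.70), se(0.70))
  expect_lt(abs(mean(p$referred) - 0.50), se(0.50))
  ref <- p[p$referred, ]
  expect_lt(abs(mean(ref$specialty == "pediatrician") - 0.22),
            3 * sqrt(0.22 * 0.78 / nrow(ref)))
  expect_lt(abs(mean(p$admitted) - 0.10), se(0.10))
  # lab visits actually happened for the routed patients
  expect_false(anyNA(p$t_lab1[p$lab_via_ed]))
})

test_that("common random numbers hold draws fixed across bed counts", {
  base <- ed_config(warm_up = 0, run_length = 200)
  arr <- generate_arrival_times(
    generate_counts(build_rate_profile(base$arrivals, 200), seed = 9),
    seed = 10)
  cfg14 <- base
  cfg14$beds <- 14
  r7 <- run_replication(base, arr, seed = 11)
  r14 <- run_replication(cfg14, arr, seed = 11)
  expect_identical(r7$patients$arrival, r14$patients$arrival)
  expect_identical(r7$patients$lab_via_ed, r14$patients$lab_via_ed)
  expect_identical(r7$patients$specialty, r14$patients$specialty)
  # same service draws, so only waiting differs; more beds cannot make the
  # average bed wait longer under identical draws
  expect_lte(mean(r14$patients$wait_bed), mean(r7$patients$wait_bed))
})

test_that("collect_stats summarizes post-warm-up patients only", {
  cfg <- uncongested_config(run_length = 48)
  arr <- constant_trace(48, 2, seed = 3)
  rep1 <- run_replication(cfg, arr, seed = 4)
  s <- collect_stats(rep1)
  expect_equal(s$n_patients, nrow(rep1$patients))
  expect_equal(s$mean_los, mean(rep1$patients$los))
  expect_equal(s$mean_bed_queue, 0)  # queue always empty when uncongested

  cut <- collect_stats(rep1, warm_up = 24)
  kept <- rep1$patients$arrival >= 24 * 60
  expect_equal(cut$n_patients, sum(kept))
  expect_equal(cut$mean_los, mean(rep1$patients$los[kept]))
  expect_error(collect_stats(rep1, warm_up = 49), "no patients")
})

test_that("hourly LOS series aligns patients to their arrival hour", {
  cfg <- uncongested_config(run_length = 12)
  arr <- constant_trace(12, 2, seed = 5)
  rep1 <- run_replication(cfg, arr, seed = 6)
  series <- hourly_los(rep1, hours = 12)
  expect_length(series, 12)
  p <- rep1$patients
  expect_equal(series[3], mean(p$los[floor(p$arrival / 60) == 2]))
})
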