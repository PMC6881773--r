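# Shared fixture builders; everything is generated in code.

# A flat calendar: uniform hour/weekday weights, no season or holiday
# effects, so every hour has rate base/24.
flat_calendar <- function(base = 75, dispersion = 0) {
  calendar_config(
    base_daily_mean = base,
    hour_weights = rep(1, 24),
    weekday_weights = rep(1, 7),
    season_multipliers = c(winter = 1, spring = 1, summer = 1, fall = 1),
    holiday_multiplier = 1,
    holidays = character(0),
    dispersion = dispersion
  )
}

# Small observation set with deterministic weather (no noise).
tiny_observations <- function(hours = 24 * 7, seed = 1,
                              config = calendar_config()) {
  generate_observations(config, horizon = hours, seed = seed)
}

# ED configuration with every capacity infinite (pure routing + service).
uncongested_config <- function(routing = list(), warm_up = 0,
                               run_length = 7500) {
  ed_config(
    beds = 10000,
    capacities = list(triage_nurse = Inf, ed_physician = Inf, lab_xray = Inf,
                      attending = c(pediatrician = Inf,
                                    otorhinolaryngology = Inf,
                                    internal_medicine = Inf,
                                    orthopedics = Inf, other = Inf)),
    routing = routing,
    warm_up = warm_up,
    run_length = run_length
  )
}

# Arrival trace with `per_hour` arrivals in each of `hours` hours.
constant_trace <- function(hours, per_hour = 3, seed = 1) {
  generate_arrival_times(rep(per_hour, hours), seed = seed)
}

# M/M/1 queue built on the engine: exponential interarrivals (rate lambda)
# and services (rate mu), run for `horizon` minutes. Returns the pieces the
# Little's-law check needs.
run_mm1 <- function(lambda, mu, horizon, seed = 1) {
  set.seed(seed)
  sim <- sim_new()
  server <- sim_resource(sim, "server", 1)
  cap <- ceiling(1.5 * lambda * horizon) + 100
  arrivals <- numeric(cap); na <- 0L
  departures <- numeric(cap); nd <- 0L
  on_grant <- function(data, wait) {
    sim_schedule(sim, sim_now(sim) + rexp(1, mu), function(d) {
      nd <<- nd + 1L
      departures[nd] <<- sim_now(sim)
      sim_release(server)
    })
  }
  arrive <- function(d) {
    t <- sim_now(sim)
    if (t <= horizon) {
      na <<- na + 1L
      arrivals[na] <<- t
      sim_schedule(sim, t + rexp(1, lambda), arrive)
      sim_seize(server, NULL, on_grant)
    }
  }
  sim_schedule(sim, rexp(1, lambda), arrive)
  sim_run(sim)
  stats <- resource_stats(server, until = horizon)
  list(arrivals = arrivals[seq_len(na)], departures = departures[seq_len(nd)],
       stats = stats, horizon = horizon)
}
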