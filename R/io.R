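#' Write hourly observations to CSV
#'
#' One row per hour with an ISO-8601 timestamp column; the exact schema that
#' [read_observations()] validates.
#'
#' @param observations An `ed_observations` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  out <- as_tibble(observations) %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate hourly observations from CSV
#'
#' Reads the documented schema (ISO-8601 `timestamp`, calendar flags,
#' `temperature`, `humidity`, `count`) and validates it: all columns
#' present, no missing values, counts non-negative, humidity within
#' \[0, 100\], the weekend flag consistent with the day of week, and the
#' hourly grid contiguous. Violations abort with the offending row numbers.
#'
#' @param path CSV file path.
#' @return An `ed_observations` tibble.
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("timestamp", "hour_of_day", "day_of_week", "weekend_flag",
           "season", "holiday_flag", "temperature", "humidity", "count")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  obs <- as_tibble(raw) %>%
    mutate(
      timestamp = as.POSIXct(.data$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ"),
      weekend_flag = as.logical(.data$weekend_flag),
      holiday_flag = as.logical(.data$holiday_flag)
    )
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      abort(sprintf("%s at row(s) %s.", what,
                    paste(utils::head(which(!ok), 5), collapse = ", ")))
    }
  }
  bad_row(!is.na(obs$timestamp), "unparseable timestamp")
  bad_row(stats::complete.cases(obs[req]), "missing value")
  bad_row(obs$count >= 0, "negative count")
  bad_row(obs$humidity >= 0 & obs$humidity <= 100, "humidity outside [0, 100]")
  bad_row(obs$weekend_flag == (obs$day_of_week >= 6),
          "weekend flag inconsistent with day of week")
  bad_row(obs$hour_of_day == lubridate::hour(obs$timestamp),
          "hour_of_day inconsistent with timestamp")
  check_hour_contiguous(obs$timestamp)
  structure(obs[req], class = c("ed_observations", class(tibble())))
}

#' Descriptive statistics of an arrival dataset
#'
#' The headline statistics a planner inspects before modelling: mean daily
#' arrivals, the weekend and evening shares of arrivals, mean hourly rates
#' on holiday vs normal hours with their ratio, season totals relative to
#' winter, and the full hour-of-day profile.
#'
#' @param observations An `ed_observations` tibble.
#' @return Object of class `arrival_report` (a list of tibbles/scalars).
#' @export
arrival_report <- function(observations) {
  obs <- as_tibble(observations)
  total <- sum(obs$count)
  n_days <- nrow(obs) / 24
  hourly <- obs %>%
    group_by(.data$hour_of_day) %>%
    summarise(share = sum(.data$count) / total, .groups = "drop")
  by_season <- obs %>%
    group_by(.data$season) %>%
    summarise(mean_rate = mean(.data$count), .groups = "drop")
  holiday_rate <- mean(obs$count[obs$holiday_flag])
  normal_rate <- mean(obs$count[!obs$holiday_flag])
  structure(
    list(
      n_hours = nrow(obs),
      daily_mean = total / n_days,
      weekend_share = sum(obs$count[obs$weekend_flag]) / total,
      evening_share = sum(obs$count[obs$hour_of_day >= 17]) / total,
      holiday_rate = holiday_rate,
      normal_rate = normal_rate,
      holiday_ratio = holiday_rate / normal_rate,
      season_rates = by_season,
      hourly_profile = hourly
    ),
    class = "arrival_report"
  )
}

#' @export
print.arrival_report <- function(x, ...) {
  cat("<arrival_report>", x$n_hours, "hours\n")
  cat(sprintf("  daily mean     : %.2f arrivals/day\n", x$daily_mean))
  cat(sprintf("  weekend share  : %.1f%%\n", 100 * x$weekend_share))
  cat(sprintf("  evening share  : %.1f%% (hours 17-23)\n",
              100 * x$evening_share))
  cat(sprintf("  hourly rate    : holiday %.2f vs normal %.2f (ratio %.2f)\n",
              x$holiday_rate, x$normal_rate, x$holiday_ratio))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> features -> select -> forecast -> simulate -> sweep
#' in order, persisting each stage under `out_dir` (CSV for tables, JSON for
#' scalars) together with a manifest recording the configuration snapshot,
#' master seed, package version and per-stage timestamps. A stage whose
#' output file already exists is re-read instead of recomputed when
#' `resume = TRUE`, so a failed run restarts from its last good stage.
#'
#' The `scale` factor shrinks the horizon, the replication count and the
#' sweep for quick smoke runs (`scale = 1` reproduces the full study
#' conditions).
#'
#' @param config An [ed_config()].
#' @param out_dir Output directory (created if absent).
#' @param years Years of synthetic data to generate.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param select_features Candidate features for the exhaustive wrapper
#'   (kept small by default so the combinatorial stage stays quick).
#' @param estimator Learner for selection (default linear model for speed;
#'   use [model_rf()] for the full wrapper).
#' @param forecast_models Named list of [forecast_model()]s to evaluate.
#' @param folds Cross-validation folds for the forecast stage.
#' @param beds Bed counts for the sweep stage.
#' @param scale Scale factor in (0, 1] applied to horizon/replications.
#' @param dry_run Validate the configuration and write nothing.
#' @param resume Re-use persisted stage outputs when present.
#' @return Invisibly, a list with the manifest and every stage result.
#' @export
pipeline_run <- function(config = ed_config(),
                         out_dir = "edsim-run",
                         years = 1,
                         seed = config$seed,
                         select_features = c("hour_of_day", "weekend_flag",
                                             "holiday_flag", "season"),
                         estimator = model_lm(),
                         forecast_models = list(mean_rate = model_mean_rate(),
                                                poisson = model_poisson(seed)),
                         folds = 10,
                         beds = 7:14,
                         scale = 1,
                         dry_run = FALSE,
                         resume = TRUE) {
  stopifnot(inherits(config, "ed_config"), scale > 0, scale <= 1)
  if (dry_run) {
    inform("dry run: configuration valid; nothing written.")
    return(invisible(list(config = config, dry_run = TRUE)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4)
  horizon <- max(24L * 14L, as.integer(floor(years * 8760 * scale)))
  reps <- max(2L, as.integer(ceiling(config$replications * scale)))
  sweep_hours <- max(200, config$run_length * scale)
  warm_up <- config$warm_up
  manifest <- list(
    command = "pipeline_run",
    version = as.character(utils::packageVersion("edsim")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    master_seed = seed,
    stage_seeds = list(generate = seeds[1], forecast = seeds[2],
                       simulate = seeds[3], sweep = seeds[4]),
    scale = scale,
    horizon_hours = horizon,
    replications = reps,
    beds = beds,
    config = unclass(jsonlite::fromJSON(jsonlite::toJSON(
      config[c("beds", "capacities", "routing", "warm_up", "run_length",
               "replications")], auto_unbox = TRUE, digits = NA)))
  )
  stage_path <- function(name, ext = "csv") file.path(out_dir,
                                                      paste0(name, ".", ext))
  log_stage <- function(name) {
    inform(sprintf("[edsim] stage=%s seed=%d t=%s", name, seed,
                   format(Sys.time(), "%H:%M:%S")))
  }

  run_stage <- function(name, compute, write, read) {
    path <- stage_path(name)
    if (resume && file.exists(path)) return(read(path))
    log_stage(name)
    value <- compute()
    write(value, path)
    value
  }

  obs <- run_stage("observations",
    compute = function() generate_observations(config$arrivals, horizon,
                                               seed = seeds[1]),
    write = write_observations,
    read = read_observations)

  feats <- run_stage("features",
    compute = function() build_feature_table(obs),
    write = function(v, p) utils::write.csv(
      v %>% mutate(timestamp = format(.data$timestamp,
                                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
      p, row.names = FALSE),
    read = function(p) {
      build_feature_table(obs)  # cheap and deterministic given obs
    })

  log_stage("select")
  sel <- exhaustive_select(feats, select_features, estimator = estimator,
                           folds = 5, seed = seeds[2])
  utils::write.csv(as_tibble(sel) %>% select(-"features"),
                   stage_path("selection"), row.names = FALSE)

  log_stage("forecast")
  cv <- purrr::map(forecast_models, kfold_evaluate, table = feats,
                   k = folds, seed = seeds[2])
  cv_tbl <- purrr::imap(cv, function(r, nm) {
    glance(r) %>% mutate(model = nm)
  }) %>% purrr::list_rbind()
  utils::write.csv(cv_tbl, stage_path("forecast"), row.names = FALSE)

  log_stage("simulate")
  wm <- warmup_replications(config, hours = max(100, 300 * scale),
                            replications = reps, seed = seeds[3])
  welch <- detect_warmup(wm, w = 1, tolerance = 0.05)
  jsonlite::write_json(
    list(warmup_hours = welch$warmup, settled = welch$settled),
    stage_path("warmup", "json"), auto_unbox = TRUE)

  log_stage("sweep")
  sweep <- bed_sweep(config, beds = beds, replications = reps,
                     hours = sweep_hours, warm_up = warm_up, seed = seeds[4])
  utils::write.csv(as_tibble(sweep), stage_path("sweep"), row.names = FALSE)
  optimum <- suppressWarnings(find_optimum_beds(sweep))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  manifest$optimum_beds <- as.integer(optimum)
  manifest$sweep_saturated <- isTRUE(attr(optimum, "saturated"))
  jsonlite::write_json(manifest, stage_path("manifest", "json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, observations = obs, features = feats,
                 selection = sel, forecast = cv, warmup = welch,
                 sweep = sweep, optimum_beds = optimum))
}
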