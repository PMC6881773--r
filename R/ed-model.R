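# Pre-draw every stochastic attribute of n patients (routing flags, triage
# class, specialty, all stage durations). Drawing everything up front from a
# patient-indexed seed is what makes common random numbers exact: a change in
# any capacity cannot perturb a single draw.
draw_patients <- function(n, config, seed) {
  rt <- config$routing
  srv <- config$service
  spec_names <- names(rt$specialty_split)
  with_local_seed(seed, {
    tibble(
      id = seq_len(n),
      ambulance = runif(n) < rt$ambulance_fraction,
      triage_class = sample(names(rt$triage_probs), n, replace = TRUE,
                            prob = rt$triage_probs),
      lab_via_ed = runif(n) < rt$p_lab_after_ed,
      referred = runif(n) < rt$p_attending,
      specialty = spec_names[sample.int(length(spec_names), n, replace = TRUE,
                                        prob = rt$specialty_split)],
      lab_after_attending = runif(n) < rt$p_lab_after_attending,
      admitted = runif(n) < rt$p_admission,
      d_triage = sample_duration(srv$triage, n),
      d_ed = sample_duration(srv$ed_exam, n),
      d_lab1 = sample_duration(srv$lab_xray, n),
      d_att = {
        d <- numeric(n)
        for (sp in spec_names) {
          idx <- which(specialty == sp)
          if (length(idx)) d[idx] <- sample_duration(srv$attending[[sp]],
                                                     length(idx))
        }
        d
      },
      d_lab2 = sample_duration(srv$lab_xray, n),
      d_stab = sample_duration(srv$stabilization, n)
    )
  })
}

#' Run one replication of the ED patient-flow simulation
#'
#' Walks every arriving patient through the ED route: non-ambulance arrivals
#' seize the triage room (UNIF(2, 4), registration folded in) while ambulance
#' arrivals skip it; all patients then see an ED physician (TRIA(5, 8, 15)),
#' visit the laboratory/X-ray with probability 0.7, are referred to an
#' attending-physician specialty with probability 0.5 (possibly revisiting
#' the lab), and finally occupy a stabilization bed *and* an attending jointly
#' for one TRIA(30, 60, 120) draw before leaving admitted or discharged.
#' Resource statistics are reset at the end of the warm-up period and
#' integrated until the end of the arrival trace; patients in flight at that
#' point still run to completion so every record has a length of stay.
#'
#' @param config An [ed_config()]; `config$beds` is the stabilization-bed
#'   capacity.
#' @param arrivals Numeric vector of arrival times in *hours* from the start
#'   of the run (e.g. from [generate_arrival_times()]), covering warm-up plus
#'   run length.
#' @param seed Integer seed for the patient-level draws.
#' @param record_queue Record the bed-queue step series (needed for
#'   time-weighted queue statistics).
#' @return Object of class `ed_replication`: list with `patients` (one row
#'   per patient: route flags, per-stage start times, waits, departure, `los`
#'   in minutes), `resources` (time-weighted post-warm-up statistics),
#'   `bed_queue` (step series, if recorded), `horizon_min` and `warm_up_min`.
#' @examples
#' cfg <- ed_config(beds = 10, warm_up = 0, run_length = 48)
#' arr <- generate_arrival_times(generate_counts(
#'   build_rate_profile(cfg$arrivals, 48), seed = 1), seed = 2)
#' rep1 <- run_replication(cfg, arr, seed = 3)
#' mean(rep1$patients$los)
#' @export
run_replication <- function(config, arrivals, seed = 1L,
                            record_queue = FALSE) {
  stopifnot(inherits(config, "ed_config"))
  horizon_min <- (config$warm_up + config$run_length) * 60
  if (length(arrivals) == 0) abort("empty arrival trace.")
  trace_hours <- attr(arrivals, "hours") %||% ceiling(max(arrivals))
  if (trace_hours < config$warm_up + config$run_length) {
    abort(sprintf(
      "arrival trace covers %.0f h but warm-up + run length need %.0f h.",
      trace_hours, config$warm_up + config$run_length))
  }
  arr_min <- sort(as.numeric(arrivals)) * 60
  n <- length(arr_min)
  p <- draw_patients(n, config, seed)

  sim <- sim_new()
  caps <- config$capacities
  r_triage <- sim_resource(sim, "triage_nurse", caps$triage_nurse)
  r_ed <- sim_resource(sim, "ed_physician", caps$ed_physician)
  r_lab <- sim_resource(sim, "lab_xray", caps$lab_xray)
  r_att <- lapply(names(caps$attending), function(sp) {
    sim_resource(sim, paste0("attending_", sp), caps$attending[[sp]])
  })
  names(r_att) <- names(caps$attending)
  r_bed <- sim_resource(sim, "bed", config$beds, record_queue = record_queue)
  r_pool <- sim_resource(sim, "attending_pool",
                         if (all(is.finite(caps$attending)))
                           sum(caps$attending) else Inf)
  stab <- sim_joint(sim, r_bed, r_pool)

  # patient attribute vectors, pulled out of the tibble for fast indexing
  amb <- p$ambulance
  lab1 <- p$lab_via_ed
  ref <- p$referred
  spec_idx <- match(p$specialty, names(r_att))
  lab2 <- p$lab_after_attending
  d_triage <- p$d_triage; d_ed <- p$d_ed; d_lab1 <- p$d_lab1
  d_att <- p$d_att; d_lab2 <- p$d_lab2; d_stab <- p$d_stab

  t_triage <- rep(NA_real_, n); w_triage <- numeric(n)
  t_ed <- rep(NA_real_, n); w_ed <- numeric(n)
  t_lab1 <- rep(NA_real_, n)
  t_att <- rep(NA_real_, n)
  t_lab2 <- rep(NA_real_, n)
  t_stab <- rep(NA_real_, n); w_stab <- numeric(n)
  t_out <- rep(NA_real_, n)

  now <- sim$time
  schedule <- sim$push  # direct heap access; sim_schedule adds a call layer
  # stage handlers; each event payload is the patient index
  g_triage <- function(i, wait) {
    w_triage[i] <<- wait
    t_triage[i] <<- now()
    schedule(now() + d_triage[i], h_triage_end, i)
  }
  h_triage_end <- function(i) {
    sim_release(r_triage)
    sim_seize(r_ed, i, g_ed)
  }
  g_ed <- function(i, wait) {
    w_ed[i] <<- wait
    t_ed[i] <<- now()
    schedule(now() + d_ed[i], h_ed_end, i)
  }
  h_ed_end <- function(i) {
    sim_release(r_ed)
    if (lab1[i]) sim_seize(r_lab, i, g_lab1) else after_ed_lab(i)
  }
  g_lab1 <- function(i, wait) {
    t_lab1[i] <<- now()
    schedule(now() + d_lab1[i], h_lab1_end, i)
  }
  h_lab1_end <- function(i) {
    sim_release(r_lab)
    after_ed_lab(i)
  }
  after_ed_lab <- function(i) {
    if (ref[i]) sim_seize(r_att[[spec_idx[i]]], i, g_att) else to_stab(i)
  }
  g_att <- function(i, wait) {
    t_att[i] <<- now()
    schedule(now() + d_att[i], h_att_end, i)
  }
  h_att_end <- function(i) {
    sim_release(r_att[[spec_idx[i]]])
    if (lab2[i]) sim_seize(r_lab, i, g_lab2) else to_stab(i)
  }
  g_lab2 <- function(i, wait) {
    t_lab2[i] <<- now()
    schedule(now() + d_lab2[i], h_lab2_end, i)
  }
  h_lab2_end <- function(i) {
    sim_release(r_lab)
    to_stab(i)
  }
  to_stab <- function(i) {
    sim_seize_joint(stab, i, g_stab)
  }
  g_stab <- function(i, wait) {
    w_stab[i] <<- wait
    t_stab[i] <<- now()
    schedule(now() + d_stab[i], h_stab_end, i)
  }
  h_stab_end <- function(i) {
    sim_release_joint(stab)
    t_out[i] <<- now()
  }

  h_arrival <- function(i) {
    if (i < n) schedule(arr_min[i + 1L], h_arrival, i + 1L)
    if (amb[i]) sim_seize(r_ed, i, g_ed) else sim_seize(r_triage, i, g_triage)
  }

  all_res <- c(list(r_triage, r_ed, r_lab, r_bed, r_pool), unname(r_att))
  warm_min <- config$warm_up * 60
  if (warm_min > 0) {
    sim_schedule(sim, warm_min, function(d) {
      for (r in all_res) sim_stats_reset(r)
    })
  }
  # snapshot resource statistics at the end of the nominal horizon
  res_tbl <- NULL
  sim_schedule(sim, horizon_min, function(d) {
    res_tbl <<- purrr::list_rbind(lapply(all_res, resource_stats))
  })
  sim_schedule(sim, arr_min[1], h_arrival, 1L)
  sim_run(sim)
  if (is.null(res_tbl)) {
    res_tbl <- purrr::list_rbind(lapply(all_res, resource_stats))
  }

  patients <- p %>%
    select("id", "ambulance", "triage_class", "lab_via_ed", "referred",
           "specialty", "lab_after_attending", "admitted") %>%
    mutate(
      specialty = ifelse(.data$referred, .data$specialty, NA_character_),
      disposition = ifelse(.data$admitted, "admitted", "discharged"),
      arrival = arr_min,
      t_triage = t_triage, t_ed = t_ed, t_lab1 = t_lab1, t_att = t_att,
      t_lab2 = t_lab2, t_stab = t_stab, departure = t_out,
      wait_ed = w_ed, wait_bed = w_stab,
      los = t_out - arr_min
    )

  structure(
    list(patients = patients,
         resources = res_tbl,
         bed_queue = if (record_queue) queue_series(r_bed),
         horizon_min = horizon_min,
         warm_up_min = warm_min),
    class = "ed_replication"
  )
}

#' @export
print.ed_replication <- function(x, ...) {
  cat("<ed_replication>", nrow(x$patients), "patients,",
      sprintf("mean LOS %.1f min\n", mean(x$patients$los, na.rm = TRUE)))
  invisible(x)
}

#' Post-warm-up scenario summary of a replication
#'
#' Summarizes patients arriving after the warm-up cut: mean length of stay,
#' time-weighted mean and maximum bed-queue length, bed utilization, and the
#' per-resource utilization table. Queue and utilization statistics come
#' from the engine's time integrals over the post-warm-up window.
#'
#' @param replication An [run_replication()] result.
#' @param warm_up Warm-up in hours (default: the value the replication was
#'   run with).
#' @return One-row tibble: `n_patients`, `mean_los`, `mean_bed_queue`,
#'   `max_bed_queue`, `bed_utilization`; the full per-resource table rides in
#'   attribute `"resources"`.
#' @export
collect_stats <- function(replication, warm_up = NULL) {
  stopifnot(inherits(replication, "ed_replication"))
  warm_min <- if (is.null(warm_up)) replication$warm_up_min else warm_up * 60
  pts <- replication$patients %>% filter(.data$arrival >= warm_min)
  if (nrow(pts) == 0) abort("no patients arrived after the warm-up period.")
  beds <- replication$resources %>% filter(.data$resource == "bed")
  out <- tibble(
    n_patients = nrow(pts),
    mean_los = mean(pts$los),
    mean_bed_wait = mean(pts$wait_bed),
    mean_bed_queue = beds$mean_queue,
    max_bed_queue = beds$max_queue,
    bed_utilization = beds$utilization
  )
  attr(out, "resources") <- replication$resources
  out
}

#' Mean length of stay per arrival hour
#'
#' The per-hour performance series fed to the Welch warm-up procedure: the
#' mean LOS of patients grouped by their arrival hour (hour 1 covers the
#' first simulated hour). Hours without arrivals give `NA`.
#'
#' @param replication An [run_replication()] result.
#' @param hours Number of hourly bins (default: the run horizon).
#' @return Numeric vector of length `hours` of mean LOS values (minutes).
#' @export
hourly_los <- function(replication, hours = NULL) {
  hours <- hours %||% ceiling(replication$horizon_min / 60)
  pts <- replication$patients
  bin <- floor(pts$arrival / 60) + 1L
  keep <- bin <= hours
  means <- tapply(pts$los[keep], bin[keep], mean)
  out <- rep(NA_real_, hours)
  out[as.integer(names(means))] <- means
  out
}
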