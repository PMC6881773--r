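#' Default ED service-time table
#'
#' Stage service distributions of the modelled emergency department, in
#' minutes: triage room (registration folded in) UNIF(2, 4); ED-physician
#' examination TRIA(5, 8, 15); laboratory / X-ray TRIA(15, 30, 45); attending
#' examinations per specialty — pediatrician TRIA(15, 20, 40),
#' otorhinolaryngology TRIA(5, 8, 20), internal medicine TRIA(15, 20, 30),
#' orthopedics TRIA(5, 10, 20), other specialties TRIA(5, 10, 15); patient
#' stabilization (bed + attending jointly) TRIA(30, 60, 120).
#'
#' @return Named list of [dist_spec] objects (`attending` is itself a named
#'   list keyed by specialty).
#' @export
default_service_table <- function() {
  list(
    triage = dist_unif(2, 4),
    ed_exam = dist_tria(5, 8, 15),
    lab_xray = dist_tria(15, 30, 45),
    attending = list(
      pediatrician = dist_tria(15, 20, 40),
      otorhinolaryngology = dist_tria(5, 8, 20),
      internal_medicine = dist_tria(15, 20, 30),
      orthopedics = dist_tria(5, 10, 20),
      other = dist_tria(5, 10, 15)
    ),
    stabilization = dist_tria(30, 60, 120)
  )
}

#' Emergency-department scenario configuration
#'
#' Bundles everything a simulation scenario needs: resource capacities,
#' routing probabilities, the service-time table, run controls and the
#' arrival-generator calendar.
#'
#' Routing defaults: 70% of patients are sent to the laboratory/X-ray by the
#' ED physician; half are referred onward to an attending physician, split
#' 22% pediatrician, 17% otorhinolaryngology, 13% internal medicine, 11%
#' orthopedics and 37% other specialties; a referred patient revisits the lab
#' with probability 0.2; 10% of patients leave admitted to hospital, the rest
#' discharged; 5% arrive by ambulance and skip the triage room. Every patient
#' ends in stabilization, which holds one bed and one attending from the
#' pooled staff simultaneously for a single service draw.
#'
#' Capacity defaults: 1 triage nurse, 2 ED physicians, 4 lab/X-ray stations,
#' one attending per named specialty plus a pool of 10 for the remaining
#' specialties (so 14 attendings in all), and 7 stabilization beds — the bed
#' count is the sweep variable.
#'
#' @param beds Stabilization bed count (>= 1); the capacity under study.
#' @param capacities Named list overriding any of `triage_nurse`,
#'   `ed_physician`, `lab_xray`, `attending` (named vector by specialty).
#' @param routing Named list overriding any of `ambulance_fraction`,
#'   `p_lab_after_ed`, `p_attending`, `specialty_split`,
#'   `p_lab_after_attending`, `p_admission`, `triage_probs`.
#' @param service Service-time table as in [default_service_table()].
#' @param warm_up Warm-up period in hours discarded from statistics.
#' @param run_length Post-warm-up run length in hours.
#' @param replications Default replication count for experiments.
#' @param arrivals A [calendar_config()] driving the synthetic arrival trace.
#' @param seed Default master seed for experiments.
#' @return Object of class `ed_config`.
#' @examples
#' cfg <- ed_config(beds = 10)
#' cfg$routing$p_lab_after_ed
#' @export
ed_config <- function(beds = 7,
                      capacities = list(),
                      routing = list(),
                      service = default_service_table(),
                      warm_up = 29,
                      run_length = 7500,
                      replications = 5,
                      arrivals = calendar_config(),
                      seed = 1L) {
  caps <- modifyList(list(
    triage_nurse = 1,
    ed_physician = 2,
    lab_xray = 4,
    attending = c(pediatrician = 1, otorhinolaryngology = 1,
                  internal_medicine = 1, orthopedics = 1, other = 10)
  ), capacities)
  rt <- modifyList(list(
    ambulance_fraction = 0.05,
    p_lab_after_ed = 0.70,
    p_attending = 0.50,
    specialty_split = c(pediatrician = 0.22, otorhinolaryngology = 0.17,
                        internal_medicine = 0.13, orthopedics = 0.11,
                        other = 0.37),
    p_lab_after_attending = 0.20,
    p_admission = 0.10,
    triage_probs = c(red = 0.05, yellow = 0.35, green = 0.60)
  ), routing)

  if (beds < 1) abort("`beds` must be >= 1.")
  probs <- c(rt$ambulance_fraction, rt$p_lab_after_ed, rt$p_attending,
             rt$p_lab_after_attending, rt$p_admission)
  if (any(probs < 0 | probs > 1)) abort("routing probabilities must be in [0, 1].")
  if (abs(sum(rt$specialty_split) - 1) > 1e-8) {
    abort("`specialty_split` must sum to 1.")
  }
  if (abs(sum(rt$triage_probs) - 1) > 1e-8) {
    abort("`triage_probs` must sum to 1.")
  }
  spec_names <- names(default_service_table()$attending)
  if (!identical(sort(names(rt$specialty_split)), sort(spec_names)) ||
      !identical(sort(names(caps$attending)), sort(spec_names))) {
    abort("specialty names must match the service table.")
  }
  if (any(unlist(caps[c("triage_nurse", "ed_physician", "lab_xray")]) < 1) ||
      any(caps$attending < 1)) {
    abort("capacities must be >= 1 (use Inf for an uncapacitated stage).")
  }
  if (warm_up < 0 || run_length <= 0) abort("invalid run controls.")

  structure(
    list(beds = beds, capacities = caps, routing = rt, service = service,
         warm_up = warm_up, run_length = run_length,
         replications = replications, arrivals = arrivals,
         seed = as.integer(seed)),
    class = "ed_config"
  )
}

#' @export
print.ed_config <- function(x, ...) {
  cat("<ed_config>\n")
  cat("  beds:", x$beds,
      "| ED physicians:", x$capacities$ed_physician,
      "| lab/X-ray:", x$capacities$lab_xray,
      "| attendings:", sum(x$capacities$attending), "\n")
  cat(sprintf("  routing: lab %.0f%%, attending %.0f%%, admission %.0f%%, ambulance %.0f%%\n",
              100 * x$routing$p_lab_after_ed, 100 * x$routing$p_attending,
              100 * x$routing$p_admission, 100 * x$routing$ambulance_fraction))
  cat("  run:", x$warm_up, "h warm-up +", x$run_length, "h x",
      x$replications, "replications\n")
  invisible(x)
}

#' Write / read an ED scenario configuration as flat key-value text
#'
#' The on-disk format is YAML-compatible flat `key: value` text with dotted
#' keys (`routing.p_lab_after_ed: 0.7`), human-diffable and stable under
#' round-tripping. Service distributions serialize as `FAMILY(a, b[, c])`
#' strings.
#'
#' @param config An [ed_config()].
#' @param path File path.
#' @return `read_ed_config()` returns an [ed_config()];
#'   `write_ed_config()` returns `path` invisibly.
#' @export
write_ed_config <- function(config, path) {
  stopifnot(inherits(config, "ed_config"))
  fmt_dist <- function(d) {
    switch(d$family,
           UNIF = sprintf("UNIF(%g, %g)", d$a, d$b),
           TRIA = sprintf("TRIA(%g, %g, %g)", d$a, d$m, d$b),
           constant = sprintf("constant(%g)", d$value),
           EXP = sprintf("EXP(%g)", d$rate))
  }
  num <- function(x) paste(format(x, digits = 15), collapse = ", ")
  lines <- c(
    sprintf("beds: %s", num(config$beds)),
    sprintf("capacities.triage_nurse: %s", num(config$capacities$triage_nurse)),
    sprintf("capacities.ed_physician: %s", num(config$capacities$ed_physician)),
    sprintf("capacities.lab_xray: %s", num(config$capacities$lab_xray)),
    sprintf("capacities.attending.%s: %s", names(config$capacities$attending),
            vapply(config$capacities$attending, num, character(1))),
    sprintf("routing.ambulance_fraction: %s", num(config$routing$ambulance_fraction)),
    sprintf("routing.p_lab_after_ed: %s", num(config$routing$p_lab_after_ed)),
    sprintf("routing.p_attending: %s", num(config$routing$p_attending)),
    sprintf("routing.p_lab_after_attending: %s", num(config$routing$p_lab_after_attending)),
    sprintf("routing.p_admission: %s", num(config$routing$p_admission)),
    sprintf("routing.specialty_split.%s: %s", names(config$routing$specialty_split),
            vapply(config$routing$specialty_split, num, character(1))),
    sprintf("routing.triage_probs.%s: %s", names(config$routing$triage_probs),
            vapply(config$routing$triage_probs, num, character(1))),
    sprintf("service.triage: %s", fmt_dist(config$service$triage)),
    sprintf("service.ed_exam: %s", fmt_dist(config$service$ed_exam)),
    sprintf("service.lab_xray: %s", fmt_dist(config$service$lab_xray)),
    sprintf("service.stabilization: %s", fmt_dist(config$service$stabilization)),
    sprintf("service.attending.%s: %s", names(config$service$attending),
            vapply(config$service$attending, fmt_dist, character(1))),
    sprintf("run.warm_up: %s", num(config$warm_up)),
    sprintf("run.run_length: %s", num(config$run_length)),
    sprintf("run.replications: %s", num(config$replications)),
    sprintf("run.seed: %s", num(config$seed))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ed_config
#' @export
read_ed_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":\\s+")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  get_num <- function(key) as.numeric(vals[keys == key])
  parse_dist <- function(s) {
    m <- regmatches(s, regexec("^(\\w+)\\(([^)]*)\\)$", s))[[1]]
    p <- as.numeric(strsplit(m[3], ",\\s*")[[1]])
    switch(m[2],
           UNIF = dist_unif(p[1], p[2]),
           TRIA = dist_tria(p[1], p[2], p[3]),
           constant = dist_const(p[1]),
           EXP = dist_exp(p[1]),
           abort(paste("unknown distribution family in", s)))
  }
  grab_named <- function(prefix, f = get_num) {
    sel <- startsWith(keys, prefix)
    setNames(lapply(which(sel), function(i) f(keys[i])),
             sub(prefix, "", keys[sel], fixed = TRUE))
  }
  att_caps <- unlist(grab_named("capacities.attending."))
  split <- unlist(grab_named("routing.specialty_split."))
  triage_p <- unlist(grab_named("routing.triage_probs."))
  att_srv <- lapply(grab_named("service.attending.",
                               f = function(k) vals[keys == k]), parse_dist)
  ed_config(
    beds = get_num("beds"),
    capacities = list(
      triage_nurse = get_num("capacities.triage_nurse"),
      ed_physician = get_num("capacities.ed_physician"),
      lab_xray = get_num("capacities.lab_xray"),
      attending = att_caps
    ),
    routing = list(
      ambulance_fraction = get_num("routing.ambulance_fraction"),
      p_lab_after_ed = get_num("routing.p_lab_after_ed"),
      p_attending = get_num("routing.p_attending"),
      p_lab_after_attending = get_num("routing.p_lab_after_attending"),
      p_admission = get_num("routing.p_admission"),
      specialty_split = split,
      triage_probs = triage_p
    ),
    service = list(
      triage = parse_dist(vals[keys == "service.triage"]),
      ed_exam = parse_dist(vals[keys == "service.ed_exam"]),
      lab_xray = parse_dist(vals[keys == "service.lab_xray"]),
      attending = att_srv,
      stabilization = parse_dist(vals[keys == "service.stabilization"])
    ),
    warm_up = get_num("run.warm_up"),
    run_length = get_num("run.run_length"),
    replications = get_num("run.replications"),
    seed = get_num("run.seed")
  )
}
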