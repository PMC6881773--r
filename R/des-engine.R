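#' Create a discrete-event simulation
#'
#' The simulation owns a clock (in minutes) and a future-event list ordered
#' by `(time, insertion sequence)`, so simultaneous events execute in
#' insertion order. State lives in a closure environment and events carry a
#' handler function plus an arbitrary data payload; scheduling into the past
#' is rejected.
#'
#' @return Object of class `ed_simulation` (an environment). Interact with it
#'   through [sim_schedule()], [sim_run()], [sim_now()], [sim_resource()],
#'   [sim_seize()] and [sim_release()].
#' @examples
#' sim <- sim_new()
#' log <- integer(0)
#' sim_schedule(sim, 5, function(d) log <<- c(log, d), 1L)
#' sim_schedule(sim, 5, function(d) log <<- c(log, d), 2L)
#' sim_run(sim)
#' log # 1 2: ties run in insertion order
#' @export
sim_new <- function() {
  ht <- numeric(1024L)          # event times
  hs <- integer(1024L)        # insertion sequence (tie-break)
  hf <- vector("list", 1024L) # handlers
  hd <- vector("list", 1024L) # payloads
  n <- 0L
  seqc <- 0L
  now <- 0

  push <- function(t, f, d) {
    if (t < now) stop("cannot schedule an event in the past.", call. = FALSE)
    n <<- n + 1L
    seqc <<- seqc + 1L
    s <- seqc
    if (n > length(ht)) {
      length(ht) <<- 2L * n; length(hs) <<- 2L * n
      length(hf) <<- 2L * n; length(hd) <<- 2L * n
    }
    i <- n
    while (i > 1L) {
      p <- i %/% 2L
      if (ht[p] > t) {
        ht[i] <<- ht[p]; hs[i] <<- hs[p]; hf[[i]] <<- hf[[p]]
        hd[i] <<- hd[p]
        i <- p
      } else break
    }
    ht[i] <<- t; hs[i] <<- s; hf[[i]] <<- f; hd[i] <<- list(d)
    invisible(NULL)
  }

  run <- function(until = Inf) {
    executed <- 0L
    while (n > 0L && ht[1L] <= until) {
      t0 <- ht[1L]; f0 <- hf[[1L]]; d0 <- hd[[1L]]
      # move last leaf to root and sift down
      t <- ht[n]; s <- hs[n]; f <- hf[[n]]; d <- hd[n]
      hd[n] <<- list(NULL)  # drop payload reference; slot stays allocated
      n <<- n - 1L
      if (n > 0L) {
        i <- 1L
        repeat {
          l <- 2L * i
          if (l > n) break
          if (l < n &&
              (ht[l + 1L] < ht[l] ||
               (ht[l + 1L] == ht[l] && hs[l + 1L] < hs[l]))) l <- l + 1L
          if (ht[l] < t || (ht[l] == t && hs[l] < s)) {
            ht[i] <<- ht[l]; hs[i] <<- hs[l]; hf[[i]] <<- hf[[l]]
            hd[i] <<- hd[l]
            i <- l
          } else break
        }
        ht[i] <<- t; hs[i] <<- s; hf[[i]] <<- f; hd[i] <<- d
      }
      now <<- t0
      executed <- executed + 1L
      f0(d0)
    }
    # exit clock: min(end time, last executed event time); an untouched
    # or exhausted-at-start run lands on the end time itself
    if (is.finite(until) && (n > 0L || executed == 0L)) now <<- until
    invisible(executed)
  }

  size <- function() n
  time <- function() now

  env <- environment()
  env$resources <- list()
  class(env) <- "ed_simulation"
  env
}

#' @export
print.ed_simulation <- function(x, ...) {
  cat("<ed_simulation> t =", x$time(), "min,", x$size(), "pending event(s),",
      length(x$resources), "resource(s)\n")
  invisible(x)
}

#' Schedule an event
#'
#' @param sim An [sim_new()] simulation.
#' @param time Absolute simulation time in minutes (>= current clock).
#' @param handler Function of one argument (the payload), called when the
#'   event fires.
#' @param data Arbitrary payload passed to the handler.
#' @export
sim_schedule <- function(sim, time, handler, data = NULL) {
  sim$push(time, handler, data)
}

#' Run the simulation
#'
#' Executes events in `(time, sequence)` order until the event list is
#' exhausted or the next event lies beyond `until`.
#'
#' @inheritParams sim_schedule
#' @param until Stop time in minutes (default `Inf` = drain the event list).
#' @return Invisibly, the number of events executed.
#' @export
sim_run <- function(sim, until = Inf) {
  if (until < sim$time()) abort("`until` lies before the current clock.")
  sim$run(until)
}

#' Current simulation clock
#' @inheritParams sim_schedule
#' @return Time in minutes.
#' @export
sim_now <- function(sim) sim$time()

# ---- capacitated resources -------------------------------------------------

#' Create a capacitated resource with a FIFO queue
#'
#' A resource grants up to `capacity` concurrent holders; further seize
#' requests wait in first-in-first-out order and are granted on release.
#' Time-weighted busy and queue-length statistics accumulate continuously and
#' can be reset (e.g. at the end of a warm-up period).
#'
#' @inheritParams sim_schedule
#' @param name Resource label.
#' @param capacity Positive integer, or `Inf` for an uncapacitated stage.
#' @param track_holders Track holder identities so that a release by a
#'   non-holder errors (small bookkeeping cost; off by default).
#' @param record_queue Record every queue-length change as a step series.
#' @return A resource object (an environment), also registered in
#'   `sim$resources`.
#' @export
sim_resource <- function(sim, name, capacity,
                         track_holders = FALSE, record_queue = FALSE) {
  if (!(is.infinite(capacity) || (capacity >= 1 && capacity == floor(capacity)))) {
    abort("`capacity` must be a positive integer or Inf.")
  }
  r <- new.env(parent = emptyenv())
  r$sim <- sim
  r$name <- name
  r$cap <- capacity
  r$busy <- 0L
  r$qd <- vector("list", 64L)  # queued payloads
  r$qg <- vector("list", 64L)  # queued grant callbacks
  r$qt <- numeric(64L)         # enqueue times
  r$qh <- 0L                   # served head index
  r$qn <- 0L                   # tail index
  r$stat_t0 <- sim$time()
  r$stat_last <- sim$time()
  r$busy_area <- 0
  r$q_area <- 0
  r$q_max <- 0L
  r$track <- track_holders
  r$holders <- if (track_holders) new.env(parent = emptyenv()) else NULL
  r$record <- record_queue
  r$rec_t <- if (record_queue) numeric(0)
  r$rec_q <- if (record_queue) integer(0)
  r$time <- sim$time  # cached clock accessor; avoids dispatch per event
  sim$resources[[name]] <- r
  r
}

res_flush <- function(r, now) {
  dt <- now - r$stat_last
  if (dt > 0) {
    r$busy_area <- r$busy_area + r$busy * dt
    r$q_area <- r$q_area + (r$qn - r$qh) * dt
    r$stat_last <- now
  }
  invisible(NULL)
}

res_record <- function(r, now) {
  if (r$record) {
    r$rec_t <- c(r$rec_t, now)
    r$rec_q <- c(r$rec_q, r$qn - r$qh)
  }
  invisible(NULL)
}

#' Seize a resource (or queue for it)
#'
#' If a server is free the grant callback runs immediately with zero wait;
#' otherwise the request joins the FIFO queue and the callback runs at grant
#' time with the accrued waiting time.
#'
#' @param res A [sim_resource()].
#' @param data Payload handed to `on_grant`.
#' @param on_grant Function `(data, wait)` run when the resource is granted.
#' @param entity Optional holder identity (needed for holder tracking).
#' @export
sim_seize <- function(res, data = NULL, on_grant, entity = NULL) {
  now <- res$time()
  if (res$busy < res$cap) {
    res_flush(res, now)
    res$busy <- res$busy + 1L
    if (res$track) hold_add(res, entity)
    on_grant(data, 0)
  } else {
    res_flush(res, now)
    i <- res$qn + 1L
    if (i > length(res$qt)) {
      length(res$qd) <- 2L * i; length(res$qg) <- 2L * i
      length(res$qt) <- 2L * i
    }
    res$qd[i] <- list(data)
    res$qg[[i]] <- on_grant
    res$qt[i] <- now
    res$qn <- i
    if (res$track) res$qd[[i]] <- list(data = data, entity = entity)
    qlen <- res$qn - res$qh
    if (qlen > res$q_max) res$q_max <- qlen
    res_record(res, now)
  }
  invisible(NULL)
}

#' Release a resource and serve the queue head
#'
#' @inheritParams sim_seize
#' @export
sim_release <- function(res, entity = NULL) {
  now <- res$time()
  if (res$busy <= 0L) abort(paste0("release of idle resource '", res$name, "'."))
  if (res$track) hold_remove(res, entity)
  res_flush(res, now)
  if (res$qn > res$qh) {
    h <- res$qh + 1L
    res$qh <- h
    item <- res$qd[[h]]
    grant <- res$qg[[h]]
    wait <- now - res$qt[h]
    res$qd[h] <- list(NULL); res$qg[h] <- list(NULL)
    res_record(res, now)
    if (res$track) {
      hold_add(res, item$entity)
      grant(item$data, wait)
    } else {
      grant(item, wait)
    }
  } else {
    res$busy <- res$busy - 1L
  }
  invisible(NULL)
}

hold_add <- function(res, entity) {
  key <- as.character(entity %||% "")
  res$holders[[key]] <- (res$holders[[key]] %||% 0L) + 1L
}

hold_remove <- function(res, entity) {
  key <- as.character(entity %||% "")
  cnt <- res$holders[[key]] %||% 0L
  if (cnt <= 0L) {
    abort(paste0("entity '", key, "' does not hold resource '",
                 res$name, "'."))
  }
  res$holders[[key]] <- cnt - 1L
}

#' Reset a resource's accumulated statistics
#'
#' Clears busy-time and queue-length integrals (and the recorded queue step
#' series) as of the current clock; used to discard the warm-up period.
#'
#' @inheritParams sim_seize
#' @export
sim_stats_reset <- function(res) {
  now <- res$time()
  res$stat_t0 <- now
  res$stat_last <- now
  res$busy_area <- 0
  res$q_area <- 0
  res$q_max <- res$qn - res$qh
  if (res$record) {
    res$rec_t <- numeric(0)
    res$rec_q <- integer(0)
    res_record(res, now)
  }
  invisible(NULL)
}

#' Time-weighted statistics of a resource
#'
#' @inheritParams sim_seize
#' @param until Right end of the integration window (default: current clock).
#' @return One-row tibble: `resource`, `capacity`, observation window,
#'   time-average busy servers and queue length, maximum queue, utilization
#'   (`NA` for uncapacitated resources).
#' @export
resource_stats <- function(res, until = res$time()) {
  res_flush(res, until)
  horizon <- until - res$stat_t0
  tibble(
    resource = res$name,
    capacity = res$cap,
    window = horizon,
    mean_busy = if (horizon > 0) res$busy_area / horizon else 0,
    mean_queue = if (horizon > 0) res$q_area / horizon else 0,
    max_queue = as.numeric(res$q_max),
    utilization = if (is.finite(res$cap) && horizon > 0) {
      res$busy_area / (res$cap * horizon)
    } else NA_real_
  )
}

#' Queue-length step series of a recording resource
#'
#' @inheritParams sim_seize
#' @return Tibble `time`, `queue` (piecewise-constant from each time on).
#' @export
queue_series <- function(res) {
  if (!res$record) abort("resource was created without `record_queue = TRUE`.")
  tibble(time = res$rec_t, queue = as.integer(res$rec_q))
}

# ---- joint (simultaneous) seize of two resources ---------------------------

#' Jointly seize two resources
#'
#' `sim_joint()` couples two resources so a request holds *both*
#' simultaneously (e.g. a stabilization bed together with an attending
#' physician) for a single service duration. Requests wait in one FIFO queue
#' until both resources have a free unit; `sim_release_joint()` releases one
#' unit of each and serves the queue head if possible. Queue statistics of
#' the joint queue accumulate on the *first* resource, which should be the
#' scarce one (the bed).
#'
#' @inheritParams sim_schedule
#' @param r1,r2 Two [sim_resource()]s; `r1` owns the joint queue statistics.
#' @return Object of class `sim_joint`.
#' @export
sim_joint <- function(sim, r1, r2) {
  structure(list(sim = sim, time = sim$time, r1 = r1, r2 = r2),
            class = "sim_joint")
}

#' @rdname sim_joint
#' @param joint A `sim_joint`.
#' @inheritParams sim_seize
#' @export
sim_seize_joint <- function(joint, data = NULL, on_grant) {
  r1 <- joint$r1; r2 <- joint$r2
  now <- joint[["time"]]()
  if (r1$busy < r1$cap && r2$busy < r2$cap) {
    res_flush(r1, now); res_flush(r2, now)
    r1$busy <- r1$busy + 1L
    r2$busy <- r2$busy + 1L
    on_grant(data, 0)
  } else {
    res_flush(r1, now)
    i <- r1$qn + 1L
    if (i > length(r1$qt)) {
      length(r1$qd) <- 2L * i; length(r1$qg) <- 2L * i
      length(r1$qt) <- 2L * i
    }
    r1$qd[i] <- list(data)
    r1$qg[[i]] <- on_grant
    r1$qt[i] <- now
    r1$qn <- i
    qlen <- r1$qn - r1$qh
    if (qlen > r1$q_max) r1$q_max <- qlen
    res_record(r1, now)
  }
  invisible(NULL)
}

#' @rdname sim_joint
#' @export
sim_release_joint <- function(joint) {
  r1 <- joint$r1; r2 <- joint$r2
  now <- joint[["time"]]()
  if (r1$busy <= 0L || r2$busy <= 0L) abort("joint release of idle resources.")
  res_flush(r1, now); res_flush(r2, now)
  if (r1$qn > r1$qh) {
    # both stay busy for the next request; only the queue shrinks
    h <- r1$qh + 1L
    r1$qh <- h
    data <- r1$qd[[h]]
    grant <- r1$qg[[h]]
    wait <- now - r1$qt[h]
    r1$qd[h] <- list(NULL); r1$qg[h] <- list(NULL)
    res_record(r1, now)
    grant(data, wait)
  } else {
    r1$busy <- r1$busy - 1L
    r2$busy <- r2$busy - 1L
  }
  invisible(NULL)
}
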