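#' Service-time distribution specifications
#'
#' Lightweight specs for the distribution families used for ED service
#' times: uniform `UNIF(a, b)`, triangular `TRIA(a, m, b)` (minimum, mode,
#' maximum; mean `(a+m+b)/3`), a degenerate constant, and exponential
#' `EXP(rate)` (used by the engine's queueing-theory validation). All
#' parameters are minutes and must be non-negative.
#'
#' @param a,b Lower / upper bounds (minutes).
#' @param m Mode of the triangular distribution, `a <= m <= b`.
#' @param value Constant duration (minutes).
#' @param rate Exponential rate (events per minute).
#' @return Object of class `dist_spec`.
#' @examples
#' dist_mean(dist_tria(30, 60, 120)) # 70
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_unif <- function(a, b) {
  if (a < 0 || b < a) abort("UNIF needs 0 <= a <= b.")
  structure(list(family = "UNIF", a = a, b = b), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_tria <- function(a, m, b) {
  if (a < 0 || m < a || b < m) abort("TRIA needs 0 <= a <= m <= b.")
  structure(list(family = "TRIA", a = a, m = m, b = b), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_const <- function(value) {
  if (value < 0) abort("constant duration must be >= 0.")
  structure(list(family = "constant", value = value), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_exp <- function(rate) {
  if (rate <= 0) abort("EXP needs rate > 0.")
  structure(list(family = "EXP", rate = rate), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(switch(x$family,
             UNIF = sprintf("UNIF(%g, %g)", x$a, x$b),
             TRIA = sprintf("TRIA(%g, %g, %g)", x$a, x$m, x$b),
             constant = sprintf("constant(%g)", x$value),
             EXP = sprintf("EXP(%g)", x$rate)), "\n")
  invisible(x)
}

#' Theoretical mean of a distribution spec
#' @param spec A [dist_spec].
#' @return Mean duration in minutes.
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
         UNIF = (spec$a + spec$b) / 2,
         TRIA = (spec$a + spec$m + spec$b) / 3,
         constant = spec$value,
         EXP = 1 / spec$rate)
}

#' Sample durations from a distribution spec
#'
#' Inverse-CDF sampling throughout: uniform and triangular draws transform a
#' single uniform variate, so common-random-number schemes stay synchronized
#' across distribution families.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws.
#' @return Numeric vector of `n` durations (minutes).
#' @export
sample_duration <- function(spec, n = 1) {
  if (!inherits(spec, "dist_spec")) abort("`spec` must be a dist_spec.")
  switch(spec$family,
    UNIF = spec$a + (spec$b - spec$a) * runif(n),
    TRIA = {
      u <- runif(n)
      a <- spec$a; m <- spec$m; b <- spec$b
      if (b == a) rep(a, n) else {
        fc <- (m - a) / (b - a)
        ifelse(u < fc,
               a + sqrt(u * (b - a) * (m - a)),
               b - sqrt((1 - u) * (b - a) * (b - m)))
      }
    },
    constant = rep(spec$value, n),
    EXP = rexp(n, spec$rate)
  )
}
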