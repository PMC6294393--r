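#' Chi-square foraging trip-time distribution
#'
#' The time a forager spends outside the nest (leave to return with food)
#' is modelled as a chi-square random variable with mean `D` minutes,
#' `F(x, D) = 1 - Q(D/2, x/2)` with `Q` the regularised upper incomplete
#' gamma ratio; equivalently the chi-square CDF with `D` degrees of
#' freedom. Fractional `D` is supported through the gamma(shape `D/2`,
#' scale 2) representation. For `D = 2` this reduces to
#' `F(x, 2) = 1 - exp(-x/2)`.
#'
#' @param x Trip duration(s) in minutes (`>= 0`).
#' @param D Mean trip time in minutes (`> 0`).
#' @return CDF values `F(x, D)`.
#' @examples
#' trip_cdf(2, D = 2)  # 1 - exp(-1)
#' @export
trip_cdf <- function(x, D) {
  if (!is.numeric(D) || length(D) != 1 || D <= 0) abort("`D` must be > 0")
  if (any(x < 0)) abort("trip durations must be nonnegative")
  pchisq(x, df = D)
}

#' Sample foraging trip times
#'
#' @param n Number of trips.
#' @param D Mean trip time in minutes.
#' @return Numeric vector of `n` i.i.d. trip durations in minutes with CDF
#'   [trip_cdf()]. Uses the current R RNG state.
#' @export
sample_trip_times <- function(n, D) {
  if (!is.numeric(D) || length(D) != 1 || D <= 0) abort("`D` must be > 0")
  if (n == 0) return(numeric())
  rchisq(n, df = D)
}

#' Expected number of active foragers outside the nest
#'
#' For departures forming a (possibly nonhomogeneous) Poisson stream of
#' rate `r_out(t')` (ants/minute, with `t' = t/60`), the number outside at
#' time `t'` is Poisson with mean
#' \deqn{E[Q(t')] = \int_0^\infty r_{out}(t' - x) (1 - F(x, D))\,dx,}
#' the infinite-server queue with chi-square service. For constant rate
#' `r*` this is `r* D`.
#'
#' @param r_out A function of one argument giving the outgoing rate in
#'   ants/minute at any time `t' - x`, or a single number for a constant
#'   rate.
#' @param D Mean trip time in minutes.
#' @param t_prime Evaluation time(s) in minutes.
#' @param upper Upper integration limit in minutes (survival mass beyond is
#'   negligible for the default).
#' @return Expected number of foragers outside at each `t_prime`.
#' @examples
#' expected_outside(2, D = 5, t_prime = 0)  # 10
#' @export
expected_outside <- function(r_out, D, t_prime = 0,
                             upper = D + 40 * sqrt(2 * D)) {
  if (is.numeric(r_out) && length(r_out) == 1) {
    rate_fun <- function(x) rep(r_out, length(x))
  } else if (is.function(r_out)) {
    rate_fun <- r_out
  } else {
    abort("`r_out` must be a function or a single number")
  }
  vapply(t_prime, function(tp) {
    val <- integrate(function(x) {
      rate_fun(tp - x) * pchisq(x, df = D, lower.tail = FALSE)
    }, 0, upper, rel.tol = 1e-9, subdivisions = 500L)
    if (!is.finite(val$value)) abort("queue integral did not converge")
    val$value
  }, numeric(1))
}

#' Incoming rate implied by an outgoing-rate history
#'
#' Returns are the departures delayed by the trip time:
#' \deqn{r_{in}(t') = \int_0^\infty r_{out}(t' - x)\,dF(x, D)
#'   = E[r_{out}(t' - X)].}
#' A constant outgoing rate is a fixed point of this map
#' (`r_in = r_out = r*`).
#'
#' @param r_out A function of one argument (rate in ants/minute) or a
#'   single number for a constant rate.
#' @param D Mean trip time in minutes.
#' @param t_prime Evaluation time(s) in minutes.
#' @param upper Upper integration limit in minutes.
#' @return Incoming rate at each `t_prime`, ants/minute.
#' @export
incoming_rate_from_outgoing <- function(r_out, D, t_prime = 0,
                                        upper = D + 40 * sqrt(2 * D)) {
  if (is.numeric(r_out) && length(r_out) == 1) {
    rate_fun <- function(x) rep(r_out, length(x))
  } else if (is.function(r_out)) {
    rate_fun <- r_out
  } else {
    abort("`r_out` must be a function or a single number")
  }
  vapply(t_prime, function(tp) {
    integrate(function(x) {
      rate_fun(tp - x) * stats::dchisq(x, df = D)
    }, 0, upper, rel.tol = 1e-9, subdivisions = 500L)$value
  }, numeric(1))
}

#' Monte-Carlo simulation of the foraging queue
#'
#' Dispatches each outgoing event into the infinite-server queue with an
#' independent chi-square trip time and returns the resulting incoming
#' (return) sequence together with the number outside over time. Oracle
#' for [expected_outside()] and [incoming_rate_from_outgoing()].
#'
#' @param out_events Outgoing [event_sequence()] (times in seconds).
#' @param D Mean trip time in minutes (trip samples are converted to
#'   seconds when scheduling returns).
#' @return A list with `in_events` (returns, seconds) and a function
#'   `n_outside(t)` counting foragers outside at time `t` seconds.
#' @export
simulate_foraging_queue <- function(out_events, D) {
  t_out <- event_times(out_events)
  trips <- 60 * sample_trip_times(length(t_out), D)
  t_in <- sort(t_out + trips)
  in_ev <- event_sequence(t_in, label = "in")
  n_outside <- function(t) {
    findInterval(t, sort(t_out)) - findInterval(t, t_in)
  }
  list(in_events = in_ev, n_outside = n_outside)
}
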