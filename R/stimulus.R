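#' Parameters of the leaky-integrator interaction stimulus
#'
#' The stimulus `s` experienced by available foragers in the nest entrance
#' chamber jumps by a fixed amount `k` with every incoming food-bearing
#' forager and decays exponentially to zero with time constant `tau`
#' (seconds): `ds/dt = -s/tau + k * lambda_in`. Between arrivals the decay
#' is exact, so trajectories are piecewise exponential.
#'
#' @param k Jump magnitude per incoming forager (dimensionless, default
#'   0.3).
#' @param tau Decay time constant in seconds (default 0.41).
#' @return A list of class `stimulus_params`.
#' @export
stimulus_params <- function(k = 0.3, tau = 0.41) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) abort("`k` must be > 0")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    abort("`tau` must be > 0")
  }
  structure(list(k = k, tau = tau), class = "stimulus_params")
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat(sprintf("<stimulus_params k = %g, tau = %g s>\n", x$k, x$tau))
  invisible(x)
}

#' Propagate the interaction stimulus through an incoming event sequence
#'
#' Computes the piecewise-exponential stimulus trajectory exactly: between
#' arrivals `s(t) = s(t_e) * exp(-(t - t_e)/tau)`, and at each arrival `s`
#' increments by `k` (by `m * k` when `m` arrivals coincide). Query values
#' at arbitrary times with [stimulus_at()]; no interpolation is involved
#' because the decay has a closed form.
#'
#' @param events Incoming [event_sequence()].
#' @param params A [stimulus_params()] object.
#' @param s0 Initial stimulus value at time `t0` (must be `>= 0`).
#' @param t0 Time origin of the trajectory (seconds, default 0).
#' @return An object of class `stimulus_trajectory` holding the jump times
#'   and post-jump values.
#' @examples
#' sp <- stimulus_params()
#' traj <- propagate_stimulus(event_sequence(0), sp)
#' stimulus_at(traj, c(0, 0.41))   # k, then k * exp(-1)
#' @export
propagate_stimulus <- function(events, params = stimulus_params(), s0 = 0,
                               t0 = 0) {
  stopifnot(inherits(params, "stimulus_params"))
  if (!is.numeric(s0) || length(s0) != 1 || s0 < 0) {
    abort("`s0` must be a single nonnegative number")
  }
  times <- event_times(events)
  if (length(times) && times[1] < t0) {
    abort("all event times must be >= t0")
  }
  k <- params$k
  tau <- params$tau
  # collapse simultaneous arrivals into one jump of multiplicity m
  if (length(times)) {
    jt <- unique(times)
    mult <- tabulate(match(times, jt))
  } else {
    jt <- numeric()
    mult <- numeric()
  }
  vals <- numeric(length(jt))
  s_prev <- s0
  t_prev <- t0
  for (i in seq_along(jt)) {
    s_prev <- s_prev * exp(-(jt[i] - t_prev) / tau) + mult[i] * k
    t_prev <- jt[i]
    vals[i] <- s_prev
  }
  structure(list(jump_times = jt, values_after_jump = vals,
                 multiplicity = mult, s0 = s0, t0 = t0, params = params),
            class = "stimulus_trajectory")
}

#' @export
print.stimulus_trajectory <- function(x, ...) {
  cat(sprintf("<stimulus_trajectory: %d jumps, s0 = %g, k = %g, tau = %g>\n",
              length(x$jump_times), x$s0, x$params$k, x$params$tau))
  invisible(x)
}

#' Evaluate a stimulus trajectory at arbitrary times
#'
#' @param traj A `stimulus_trajectory` from [propagate_stimulus()].
#' @param t Numeric vector of query times (seconds). At a jump time the
#'   post-jump value is returned.
#' @return Numeric vector of stimulus values.
#' @export
stimulus_at <- function(traj, t) {
  stopifnot(inherits(traj, "stimulus_trajectory"))
  tau <- traj$params$tau
  idx <- findInterval(t, traj$jump_times)
  base_t <- ifelse(idx == 0, traj$t0, traj$jump_times[pmax(idx, 1)])
  base_s <- ifelse(idx == 0, traj$s0, traj$values_after_jump[pmax(idx, 1)])
  out <- base_s * exp(-(t - base_t) / tau)
  out[t < traj$t0] <- NA_real_
  out
}

#' @export
tidy.stimulus_trajectory <- function(x, ...) {
  tibble(time_s = x$jump_times, s = x$values_after_jump,
         multiplicity = x$multiplicity)
}

#' Stationary mean and variance of the shot-noise stimulus
#'
#' For a homogeneous Poisson incoming stream of rate `r_in`, the stationary
#' stimulus is a filtered Poisson (shot-noise) process and Campbell's
#' theorem gives `mean = r_in * k * tau` and `variance =
#' r_in * k^2 * tau / 2`.
#'
#' @param r_in Incoming rate in ants/sec (`>= 0`).
#' @param params A [stimulus_params()] object.
#' @return A tibble with columns `mean` and `variance`.
#' @export
stationary_moments <- function(r_in, params = stimulus_params()) {
  stopifnot(inherits(params, "stimulus_params"))
  if (!is.numeric(r_in) || any(r_in < 0)) {
    abort("`r_in` must be nonnegative")
  }
  tibble(mean = r_in * params$k * params$tau,
         variance = r_in * params$k^2 * params$tau / 2)
}

#' Stationary probability density of the stimulus
#'
#' Computes the stationary law of the shot-noise stimulus under a Poisson
#' incoming stream of rate `r_in`. The analytic method solves the
#' level-crossing balance `(s/tau) p(s) = r_in * integral of p over
#' (max(0, s - k), s)`: on the first interval `(0, k)` the solution is
#' exactly proportional to `s^(r_in * tau - 1)` (integrably divergent at 0
#' when `r_in * tau < 1`), and on each subsequent interval
#' `[n k, (n + 1) k)` the balance is marched forward as a recurrence using
#' an implicit trapezoidal update of the cumulative integral. The density
#' is continuous for `s > 0` with derivative kinks at the breakpoints
#' `s = n k`, and is normalised numerically over a truncated support whose
#' upper end is set by the exponential tail decay.
#'
#' The `"mc"` method instead draws independent stationary samples (see
#' [sample_stationary_stimulus()]) and returns a histogram density on the
#' same grid; it serves as a long-run simulation fallback and oracle.
#'
#' @param r_in Incoming Poisson rate, ants/sec (`> 0`).
#' @param params A [stimulus_params()] object.
#' @param method `"analytic"` (level-crossing recurrence) or `"mc"`
#'   (histogram of stationary samples).
#' @param points_per_interval Grid resolution of each `k`-wide interval.
#' @param s_max Truncation of the support; defaults to
#'   `max(2 * (a + 1/3), mean + 10 * sd)` rounded up to a whole number of
#'   intervals (the first term keeps the support comfortably beyond the
#'   upper excitability bifurcation at any volatility).
#' @param n_mc Number of Monte-Carlo samples for `method = "mc"`.
#' @return A tibble of class `stimulus_density` with columns `s`, `density`
#'   and `cdf`.
#' @examples
#' d <- stationary_density(2)
#' sum(d$density * diff(c(0, d$s)))  # ~ 1
#' @export
stationary_density <- function(r_in, params = stimulus_params(),
                               method = c("analytic", "mc"),
                               points_per_interval = 400, s_max = NULL,
                               n_mc = 1e5) {
  stopifnot(inherits(params, "stimulus_params"))
  method <- match.arg(method)
  if (!is.numeric(r_in) || length(r_in) != 1 || r_in <= 0) {
    abort("`r_in` must be a single positive rate")
  }
  k <- params$k
  tau <- params$tau
  mom <- stationary_moments(r_in, params)
  if (is.null(s_max)) {
    s_max <- max(2 * (0.35 + 1 / 3), mom$mean + 10 * sqrt(mom$variance))
  }
  m <- as.integer(points_per_interval)
  n_int <- max(2L, as.integer(ceiling(s_max / k)))
  h <- k / m
  s <- seq(h, n_int * k, by = h)

  if (method == "mc") {
    x <- sample_stationary_stimulus(n_mc, r_in, params)
    breaks <- c(0, s)
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = FALSE),
                    nbins = length(s))
    dens <- cnt / (n_mc * h)
    out <- tibble(s = s, density = dens, cdf = cumsum(cnt) / n_mc)
  } else {
    alpha <- r_in * tau
    p <- numeric(length(s))
    cum <- numeric(length(s)) # cumulative integral of (unnormalised) p
    first <- s <= k + 1e-12
    p[first] <- s[first]^(alpha - 1)
    cum[first] <- s[first]^alpha / alpha # exact on the first interval
    for (jj in which(!first)) {
      sk <- s[jj] - k
      # s grid is aligned with k so s - k falls on a grid point
      j0 <- as.integer(round(sk / h))
      cum_k <- if (j0 < 1) 0 else cum[j0]
      rhs <- (alpha / s[jj]) * (cum[jj - 1] + h / 2 * p[jj - 1] - cum_k)
      p[jj] <- rhs / (1 - alpha * h / (2 * s[jj]))
      cum[jj] <- cum[jj - 1] + h / 2 * (p[jj - 1] + p[jj])
    }
    z <- cum[length(cum)]
    out <- tibble(s = s, density = p / z, cdf = cum / z)
  }
  class(out) <- c("stimulus_density", class(out))
  attr(out, "r_in") <- r_in
  attr(out, "params") <- params
  attr(out, "method") <- method
  attr(out, "h") <- h
  out
}

#' Draw independent samples from the stationary stimulus law
#'
#' Each sample superposes the decayed jumps of a Poisson number of arrivals
#' with uniform ages over a window of `40 * tau` seconds (the truncation
#' error `exp(-40)` is negligible). Uses the current R RNG state.
#'
#' @param n Number of samples.
#' @param r_in Incoming Poisson rate, ants/sec.
#' @param params A [stimulus_params()] object.
#' @return Numeric vector of `n` stationary stimulus values.
#' @export
sample_stationary_stimulus <- function(n, r_in, params = stimulus_params()) {
  stopifnot(inherits(params, "stimulus_params"))
  .shot_noise_samples_cpp(as.integer(n), r_in, params$k, params$tau,
                          40 * params$tau)
}

#' Interpolate a stationary density at arbitrary stimulus values
#'
#' @param dens A `stimulus_density` from [stationary_density()].
#' @param s Values at which to evaluate the density (0 outside the grid).
#' @return Numeric vector of density values.
#' @export
density_at <- function(dens, s) {
  stopifnot(inherits(dens, "stimulus_density"))
  out <- approx(dens$s, dens$density, xout = s, yleft = NA, yright = 0)$y
  # below the first grid point use the exact power-law form
  low <- !is.na(s) & s < dens$s[1]
  if (any(low)) {
    r_in <- attr(dens, "r_in")
    params <- attr(dens, "params")
    alpha <- r_in * params$tau
    scale <- dens$density[1] / dens$s[1]^(alpha - 1)
    out[low] <- ifelse(s[low] > 0, scale * s[low]^(alpha - 1), 0)
  }
  out
}
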