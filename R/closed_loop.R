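#' Configuration of a closed-loop colony simulation
#'
#' Gathers the parameters of a full closed-loop run with the
#' informed/uninformed volatility mechanism: a colony of `N` foragers, all
#' initially uninformed with volatility `c_u`; foragers that have completed
#' at least one trip are informed with volatility `c_i`. Two FN units share
#' the common stimulus; their spike trains are blended by thinning with the
#' instantaneous informed fraction `x_i`. Foraging trips last
#' `60 * chisq(D)` seconds and every return bumps the stimulus and appends
#' an incoming event.
#'
#' @param c_u,c_i Uninformed and informed volatilities (`> 0`).
#' @param N Total number of foragers (`>= 1`).
#' @param D Mean foraging trip time in minutes.
#' @param stim A [stimulus_params()] object.
#' @param fn Template [fn_params()] whose `a`, `eps1`, `eps2` and threshold
#'   are shared by both units (its `c` is ignored).
#' @param duration Simulated time in seconds (default 3 hours).
#' @param seed Optional integer seed applied by [run_closed_loop()].
#' @param initial_incoming Exogenous incoming [event_sequence()] that
#'   primes the stimulus (it does not touch the forager pools). Defaults to
#'   a sparse Poisson stream of `initial_rate` ants/sec over the first
#'   `60 * (D + 1)` seconds, drawn when the simulation runs and
#'   conditioned on containing at least one arrival (it stands in for a
#'   recorded morning arrival sequence, which is nonempty by
#'   construction).
#' @param initial_rate Mean rate of the default priming stream (ants/sec).
#' @param dt Integration step in seconds.
#' @return A list of class `colony_config`.
#' @export
colony_config <- function(c_u, c_i, N, D, stim = stimulus_params(),
                          fn = fn_params(c = 1), duration = 3 * 3600,
                          seed = NULL, initial_incoming = NULL,
                          initial_rate = 0.01, dt = NULL) {
  if (!is.numeric(c_u) || c_u <= 0 || !is.numeric(c_i) || c_i <= 0) {
    abort("volatilities `c_u` and `c_i` must be positive")
  }
  if (!is.numeric(N) || N < 1) abort("`N` must be >= 1")
  if (!is.numeric(D) || D <= 0) abort("`D` must be > 0")
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0")
  stopifnot(inherits(stim, "stimulus_params"), inherits(fn, "fn_params"))
  if (is.null(dt)) dt <- min(fn$eps1 * fn$eps2 / 10, 1e-3)
  structure(list(c_u = c_u, c_i = c_i, N = as.integer(N), D = D,
                 stim = stim, fn = fn, duration = duration, seed = seed,
                 initial_incoming = initial_incoming,
                 initial_rate = initial_rate, dt = dt),
            class = "colony_config")
}

#' @export
print.colony_config <- function(x, ...) {
  cat(sprintf(
    "<colony_config c_u = %g, c_i = %g, N = %d, D = %g min, %.2g h>\n",
    x$c_u, x$c_i, x$N, x$D, x$duration / 3600))
  invisible(x)
}

#' Run the closed-loop colony simulation
#'
#' Integrates the two FN units (volatilities `c_u`, `c_i`) against the
#' common leaky-integrator stimulus. Each suprathreshold oscillation of the
#' uninformed unit is kept with probability `1 - x_i` and, if kept, sends
#' one uninformed forager out; informed-unit spikes are kept with
#' probability `x_i` and draw from the informed pool. A spike whose pool is
#' empty is dropped (counted in the record). A departing forager returns
#' after a chi-square trip of mean `D` minutes, joins the informed pool
#' (informed status is never lost), bumps the stimulus by `k` and appends
#' an incoming event. Exogenous priming arrivals bump the stimulus only.
#' `x_i` is recomputed after every departure and return; when no foragers
#' are available it retains its last value. Simultaneous spikes of the two
#' units are processed uninformed-first with independent thinning draws.
#'
#' @param config A [colony_config()].
#' @return A list of class `sim_record` with elements:
#' \describe{
#'   \item{lambda_in}{incoming [event_sequence()] (exogenous + returns)}
#'   \item{lambda_out}{outgoing departures, with per-event class}
#'   \item{lambda_u, lambda_i}{all spikes of each FN unit (pre-thinning)}
#'   \item{trace}{tibble `time_s`, `s`, `x_i`, `n_u`, `n_i`, `q` sampled
#'     once per second}
#'   \item{dropped}{counts of pool-empty dropped spikes}
#' }
#' @examples
#' \donttest{
#' cfg <- colony_config(c_u = 3, c_i = 0.9, N = 500, D = 5,
#'                      duration = 1800, seed = 1)
#' rec <- run_closed_loop(cfg)
#' qss_estimate(rec, tail_fraction = 0.3)
#' }
#' @export
run_closed_loop <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  exog <- config$initial_incoming
  if (is.null(exog)) {
    # the priming stream emulates a recorded morning arrival sequence,
    # which contains at least one arrival by construction; condition the
    # sparse Poisson draw on being nonempty (an empty one cannot start
    # the colony at all)
    for (attempt in 1:100) {
      exog <- generate_poisson_events(config$initial_rate,
                                      60 * (config$D + 1), label = "in")
      if (nrow(exog) > 0 || config$initial_rate == 0) break
    }
  }
  fn <- config$fn
  res <- .closed_loop_cpp(config$c_u, config$c_i, fn$a, fn$eps1, fn$eps2,
                          fn$spike_threshold, config$stim$k,
                          config$stim$tau, config$D, config$N,
                          config$duration, config$dt, exog$time_s, 1.0)
  if (res$dropped_uninformed + res$dropped_informed > 0) {
    warn(sprintf(
      "%d uninformed and %d informed spikes dropped (empty pool)",
      res$dropped_uninformed, res$dropped_informed))
  }
  out <- tibble(time_s = res$out_times,
                class = ifelse(res$out_class == 1, "informed",
                               "uninformed"))
  out <- out[order(out$time_s), ] # unit spikes within a step can interleave
  lam_in <- tibble(
    time_s = c(exog$time_s, res$return_times),
    source = c(rep("exogenous", nrow(exog)),
               rep("return", length(res$return_times))))
  lam_in <- lam_in[order(lam_in$time_s), ]
  trace <- tibble(time_s = res$trace_t, s = res$trace_s,
                  x_i = res$trace_x_i, n_u = res$trace_n_u,
                  n_i = res$trace_n_i, q = res$trace_q)
  structure(list(
    lambda_in = lam_in,
    lambda_out = out,
    lambda_u = event_sequence(res$lambda_u, label = "out"),
    lambda_i = event_sequence(res$lambda_i, label = "out"),
    trace = trace,
    dropped = c(uninformed = res$dropped_uninformed,
                informed = res$dropped_informed),
    pending_returns = res$pending_returns,
    final = list(n_u = res$n_u, n_i = res$n_i),
    config = config), class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf(
    "<sim_record: %d out, %d in (%d exogenous), %d outside at end>\n",
    nrow(x$lambda_out), nrow(x$lambda_in),
    sum(x$lambda_in$source == "exogenous"),
    x$config$N - x$final$n_u - x$final$n_i))
  invisible(x)
}

#' @export
tidy.sim_record <- function(x, window = 300, ...) {
  grid <- x$trace$time_s
  r_in <- estimate_rate(tibble(time_s = x$lambda_in$time_s), grid,
                        window = window)
  r_out <- estimate_rate(tibble(time_s = x$lambda_out$time_s), grid,
                         window = window)
  dplyr::mutate(x$trace, r_in = r_in$rate, r_out = r_out$rate)
}

#' @export
glance.sim_record <- function(x, ...) qss_estimate(x)

#' Quasi steady-state estimate from a simulation record
#'
#' Averages the 300-second windowed incoming and outgoing rates over the
#' final `tail_fraction` of the run, together with the mean number of
#' foragers outside. The gap `|r_in - r_out|` is reported as an
#' equilibration diagnostic; at a genuine QSS the two rates agree closely.
#'
#' @param record A `sim_record` from [run_closed_loop()], or any list with
#'   `lambda_in`/`lambda_out` data frames (column `time_s`) and a `trace`
#'   with `time_s` and `q`.
#' @param tail_fraction Fraction of the run, from the end, to average over
#'   (default 1/3, i.e. the final hour of a 3-hour run).
#' @param window Rate-estimation window in seconds.
#' @return A tibble with columns `r_in_qss`, `r_out_qss`, `r_qss` (their
#'   mean, ants/sec), `q_qss` (ants outside), `rate_gap` and
#'   `rate_gap_rel`.
#' @export
qss_estimate <- function(record, tail_fraction = 1 / 3, window = 300) {
  if (tail_fraction <= 0 || tail_fraction > 1) {
    abort("`tail_fraction` must be in (0, 1]")
  }
  duration <- max(record$trace$time_s)
  t_from <- duration * (1 - tail_fraction)
  if (duration - t_from < window - 1e-6) {
    abort("record too short for the requested tail and window")
  }
  grid <- seq(t_from, duration, by = min(10, window / 10))
  r_in <- estimate_rate(tibble(time_s = record$lambda_in$time_s), grid,
                        window = window, t_start = 0, t_end = duration)
  r_out <- estimate_rate(tibble(time_s = record$lambda_out$time_s), grid,
                         window = window, t_start = 0, t_end = duration)
  q_tail <- record$trace$q[record$trace$time_s >= t_from]
  r_in_qss <- mean(r_in$rate)
  r_out_qss <- mean(r_out$rate)
  r_qss <- (r_in_qss + r_out_qss) / 2
  tibble(r_in_qss = r_in_qss, r_out_qss = r_out_qss, r_qss = r_qss,
         q_qss = mean(q_tail),
         rate_gap = abs(r_in_qss - r_out_qss),
         rate_gap_rel = abs(r_in_qss - r_out_qss) / max(r_qss,
                                                        .Machine$double.eps))
}
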