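#' Analytic nest input/output curve
#'
#' The open-loop map from a constant mean incoming rate to the mean
#' outgoing rate at volatility `c`. Because the stimulus process is
#' ergodic, the fraction of time the FN unit spends oscillating is read off
#' the stationary stimulus density, and the outgoing rate is the average
#' oscillation frequency over the oscillating band:
#' \deqn{\bar r_{out} = \int_{b_1(c)}^{b_2(c)}
#'   \frac{p(s, \bar r_{in})}{T_{LC}(s, c)}\,ds.}
#' The curve rises steeply at low incoming rate (every arrival excites at
#' least one departure), peaks where the stimulus dwells mostly inside the
#' oscillating band, and falls at high incoming rate where the unit
#' saturates.
#'
#' @param c Volatility.
#' @param r_in_grid Incoming rates (ants/sec) at which to evaluate the
#'   curve.
#' @param stim A [stimulus_params()] object.
#' @param fn Template [fn_params()] (its `c` is ignored in favour of `c`).
#' @param correction Use the fold-delay-corrected period (default `TRUE`,
#'   see [lc_period()]).
#' @param points_per_interval Density grid resolution.
#' @return A tibble of class `nest_io_curve` with columns `r_in`, `r_out`;
#'   attributes `c` and `mode = "analytic"`.
#' @examples
#' \donttest{
#' curve <- nest_io_curve_analytic(2, r_in_grid = seq(0.1, 5, length = 12))
#' }
#' @export
nest_io_curve_analytic <- function(c, r_in_grid = seq(0.1, 5, length.out = 12),
                                   stim = stimulus_params(),
                                   fn = fn_params(c = 1),
                                   correction = TRUE,
                                   points_per_interval = 400) {
  if (any(r_in_grid <= 0)) abort("`r_in_grid` must be positive")
  pars <- fn_params(c = c, a = fn$a, eps1 = fn$eps1, eps2 = fn$eps2,
                    spike_threshold = fn$spike_threshold)
  b <- bifurcation_points(pars)
  # the period factor does not depend on r_in: precompute it on the band
  # portion of the (r_in-independent) aligned density grid
  h <- stim$k / points_per_interval
  s_all <- seq(h, ceiling(b[["b2"]] / h + 1) * h, by = h)
  band_idx <- which(s_all > b[["b1"]] & s_all < b[["b2"]])
  s_band <- s_all[band_idx]
  inv_T <- 1 / lc_period(s_band, pars, correction = correction)
  eps <- 1e-9
  inv_T_b1 <- 1 / lc_period(b[["b1"]] + eps, pars, correction = correction)
  inv_T_b2 <- 1 / lc_period(b[["b2"]] - eps, pars, correction = correction)
  r_out <- vapply(r_in_grid, function(r) {
    dens <- stationary_density(r, stim,
                               points_per_interval = points_per_interval)
    p_band <- dens$density[band_idx]
    freq <- p_band * inv_T
    val <- sum((freq[-1] + freq[-length(freq)]) / 2 * diff(s_band))
    f_b1 <- density_at(dens, b[["b1"]]) * inv_T_b1
    f_b2 <- density_at(dens, b[["b2"]]) * inv_T_b2
    val +
      (s_band[1] - b[["b1"]]) * (f_b1 + freq[1]) / 2 +
      (b[["b2"]] - s_band[length(s_band)]) * (f_b2 + freq[length(freq)]) / 2
  }, numeric(1))
  out <- tibble(r_in = r_in_grid, r_out = r_out)
  class(out) <- c("nest_io_curve", class(out))
  attr(out, "c") <- c
  attr(out, "mode") <- "analytic"
  out
}

#' Simulated nest input/output curve
#'
#' Open-loop Monte-Carlo counterpart of [nest_io_curve_analytic()]: for
#' each incoming rate, `trials` independent Poisson arrival streams of
#' `trial_len` seconds drive the stimulus/FN pipeline and the mean outgoing
#' count per trial length is recorded with its standard error.
#'
#' @param c Volatility.
#' @param r_in_grid Incoming rates (ants/sec); default 12 points spanning
#'   `[0.1, 5]`.
#' @param trials Number of trials per grid point (default 10).
#' @param trial_len Trial length in seconds (default 300).
#' @param stim,fn As in [nest_io_curve_analytic()].
#' @param dt Integration step passed to [simulate_fn()].
#' @return A tibble of class `nest_io_curve` with columns `r_in`, `r_out`,
#'   `se`; attributes `c` and `mode = "simulated"`. Uses the current R RNG
#'   state.
#' @export
nest_io_curve_simulated <- function(c,
                                    r_in_grid = seq(0.1, 5, length.out = 12),
                                    trials = 10, trial_len = 300,
                                    stim = stimulus_params(),
                                    fn = fn_params(c = 1), dt = NULL) {
  pars <- fn_params(c = c, a = fn$a, eps1 = fn$eps1, eps2 = fn$eps2,
                    spike_threshold = fn$spike_threshold)
  res <- vapply(r_in_grid, function(r) {
    counts <- vapply(seq_len(trials), function(i) {
      ev <- generate_poisson_events(r, trial_len)
      traj <- propagate_stimulus(ev, stim)
      sim <- simulate_fn(pars, traj, duration = trial_len, dt = dt,
                         record_dt = 0)
      nrow(sim$spikes)
    }, numeric(1))
    rates <- counts / trial_len
    c(mean(rates), stats::sd(rates) / sqrt(trials))
  }, numeric(2))
  out <- tibble(r_in = r_in_grid, r_out = res[1, ], se = res[2, ])
  class(out) <- c("nest_io_curve", class(out))
  attr(out, "c") <- c
  attr(out, "mode") <- "simulated"
  out
}

#' Two-population nest input/output curve
#'
#' With an informed fraction `x_i`, outgoing spikes are the thinned blend
#' of the uninformed (`c_u`, weight `1 - x_i`) and informed (`c_i`, weight
#' `x_i`) units responding to the same stimulus, so the mean outgoing rate
#' is the convex combination of the two single-volatility analytic curves.
#'
#' @param c_u,c_i Uninformed and informed volatilities.
#' @param x_i Informed fraction in `[0, 1]`.
#' @param r_in_grid Incoming rates (ants/sec).
#' @param ... Passed to [nest_io_curve_analytic()].
#' @return A `nest_io_curve` tibble (mode `"analytic"`).
#' @export
two_population_io <- function(c_u, c_i, x_i,
                              r_in_grid = seq(0.1, 5, length.out = 12),
                              ...) {
  if (!is.numeric(x_i) || length(x_i) != 1 || x_i < 0 || x_i > 1) {
    abort("`x_i` must lie in [0, 1]")
  }
  cu_curve <- nest_io_curve_analytic(c_u, r_in_grid, ...)
  ci_curve <- nest_io_curve_analytic(c_i, r_in_grid, ...)
  out <- tibble(r_in = r_in_grid,
                r_out = (1 - x_i) * cu_curve$r_out + x_i * ci_curve$r_out)
  class(out) <- c("nest_io_curve", class(out))
  attr(out, "c") <- c(c_u = c_u, c_i = c_i, x_i = x_i)
  attr(out, "mode") <- "analytic"
  out
}

#' Fixed points of the closed-loop iterated rate map
#'
#' The closed loop iterates the nest I/O curve: the mean incoming rate
#' becomes, one loop traversal later, the mean outgoing rate. Diagonal
#' crossings of the curve are the candidate steady-state foraging rates.
#' Crossings are located by bracketing sign changes of the
#' linearly-interpolated `r_out - r_in` and polished by bisection;
#' stability is classified by the local slope (`|G'| < 1` stable), with
#' near-tangent crossings flagged as marginal. The origin is always a
#' fixed-point candidate: its stability follows the initial slope of the
#' curve. An independent cobweb iteration from several starting rates is
#' run as a cross-check.
#'
#' @param curve A `nest_io_curve` (analytic mode recommended; the curve
#'   should start near `r_in = 0` and extend past the expected crossing).
#' @param slope_tol Band around slope 1 treated as marginal/tangent.
#' @return A list of class `iterated_map_result` with a `fixed_points`
#'   tibble (`rate`, `slope`, `stability`), the attracting rate `r_star`
#'   (0 if none), and `cobweb` (tibble of iteration endpoints).
#' @export
fixed_points <- function(curve, slope_tol = 0.05) {
  stopifnot(inherits(curve, "nest_io_curve"))
  r_in <- curve$r_in
  r_out <- curve$r_out
  g <- function(r) approx(r_in, r_out, xout = r, yleft = 0, rule = 2)$y
  diff_fun <- function(r) g(r) - r
  # scan a fine grid for sign changes (interior crossings)
  grid <- seq(min(r_in), max(r_in), length.out = 2000)
  d <- diff_fun(grid)
  idx <- which(d[-1] * d[-length(d)] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(diff_fun, c(grid[i], grid[i + 1]), tol = 1e-8)$root
  }, numeric(1))
  hs <- max(diff(r_in)) / 4
  slope_at <- function(r) (g(r + hs) - g(r - hs)) / (2 * hs)
  classify <- function(sl) {
    if (abs(abs(sl) - 1) < slope_tol) "marginal"
    else if (abs(sl) < 1) "stable"
    else "unstable"
  }
  # origin: classified by the initial slope of the curve
  slope0 <- g(r_in[1]) / r_in[1]
  fp <- tibble(rate = c(0, roots),
               slope = c(slope0, vapply(roots, slope_at, numeric(1))))
  fp$stability <- vapply(fp$slope, classify, character(1))
  nontrivial <- fp$rate > 1e-6 & fp$stability == "stable"
  r_star <- if (any(nontrivial)) max(fp$rate[nontrivial]) else 0
  # cobweb iteration cross-check
  cobweb <- do.call(rbind, lapply(c(0.05, 1, 3), function(r0) {
    r <- r0
    for (i in 1:400) r <- g(r)
    tibble(r0 = r0, r_limit = r)
  }))
  structure(list(fixed_points = fp, r_star = r_star, cobweb = cobweb,
                 curve = curve), class = "iterated_map_result")
}

#' @export
print.iterated_map_result <- function(x, ...) {
  cat("<iterated_map_result>\n")
  print(x$fixed_points)
  cat(sprintf("attracting rate r* = %g ants/sec\n", x$r_star))
  invisible(x)
}

#' @export
tidy.iterated_map_result <- function(x, ...) x$fixed_points

#' @export
glance.iterated_map_result <- function(x, ...) {
  tibble(r_star = x$r_star, n_fixed_points = nrow(x$fixed_points))
}

#' Critical volatility bound for sustained foraging
#'
#' A single isolated arrival raises the stimulus to `k`, eliciting one
#' immediate departure; the stimulus then decays and further departures
#' require one full oscillation period each while `s` stays above `b1(c)`.
#' The number of oscillations per isolated arrival is therefore at most
#' \deqn{1 + \frac{-\tau \log(b_1(c)/k)}{T_{LC}},}
#' and the critical volatility bound is the root in `c` of this expression
#' equalling 2: below the root a second departure per arrival is
#' impossible, so the nest I/O curve cannot rise above the diagonal at low
#' incoming rate. The period convention is exposed: `s_convention` picks
#' the `s` at which `T_LC` is evaluated (the default `"min"` takes the
#' minimum period over the decay range `(b1, min(k, b2)]`, matching the
#' "at most" character of the bound; at the defaults this minimum is at
#' `s = k`), `correction` selects the fold-delay-corrected or leading-order
#' period, and `count_initial_spike` controls whether the immediate
#' first departure is counted (if not, the decay window must fit two full
#' periods).
#'
#' @param stim A [stimulus_params()] object.
#' @param fn Template [fn_params()] (its `c` is ignored).
#' @param s_convention `"min"`, `"k"` (evaluate at `s = k`) or `"mid"`
#'   (band midpoint `s = a`).
#' @param correction Fold-delay-corrected period (default `TRUE`).
#' @param count_initial_spike Count the departure elicited by the arrival
#'   jump itself (default `TRUE`).
#' @param interval Search interval for the root.
#' @return The root `c_hat`, with the convention recorded in attributes.
#' @examples
#' \donttest{
#' critical_volatility()  # ~ 0.53 at defaults
#' }
#' @export
critical_volatility <- function(stim = stimulus_params(),
                                fn = fn_params(c = 1),
                                s_convention = c("min", "k", "mid"),
                                correction = TRUE,
                                count_initial_spike = TRUE,
                                interval = NULL) {
  s_convention <- match.arg(s_convention)
  k <- stim$k
  tau <- stim$tau
  if (is.null(interval)) interval <- c(0.02, 0.98 / fn$eps2)
  target <- if (count_initial_spike) 1 else 2
  count_excess <- function(c) {
    pars <- fn_params(c = c, a = fn$a, eps1 = fn$eps1, eps2 = fn$eps2,
                      spike_threshold = fn$spike_threshold)
    b <- bifurcation_points(pars)
    if (k <= b["b1"]) return(-target) # no oscillation at all
    s_eval <- switch(s_convention,
      k = min(k, b[["b2"]] - 1e-9),
      mid = (b[["b1"]] + b[["b2"]]) / 2,
      min = {
        # T_LC decreases towards the band midpoint a; on (b1, min(k, b2)]
        # the period minimum is at the upper end of the range
        min(k, b[["b2"]] - 1e-9)
      })
    (-tau * log(b[["b1"]] / k)) / lc_period(s_eval, pars,
                                            correction = correction) -
      target
  }
  # the bound rises from 0, crosses the target once, and collapses again
  # when b1(c) approaches k; bracket the lowest crossing by a scan
  grid <- seq(interval[1], interval[2], length.out = 400)
  vals <- vapply(grid, count_excess, numeric(1))
  cross <- which(vals[-1] * vals[-length(vals)] < 0)
  if (!length(cross)) {
    abort("no root of the oscillation-count bound in the search interval")
  }
  i <- cross[1]
  root <- uniroot(count_excess, c(grid[i], grid[i + 1]), tol = 1e-8)$root
  structure(root,
            s_convention = s_convention, correction = correction,
            count_initial_spike = count_initial_spike,
            class = "critical_volatility")
}

#' @export
print.critical_volatility <- function(x, ...) {
  cat(sprintf(
    "critical volatility bound c_hat = %.4f\n  (s convention '%s', %s period, initial spike %s)\n",
    unclass(x), attr(x, "s_convention"),
    if (attr(x, "correction")) "fold-delay corrected" else "leading-order",
    if (attr(x, "count_initial_spike")) "counted" else "not counted"))
  invisible(x)
}

#' Bracket the exact critical volatility of the iterated map
#'
#' Bisects on "the analytic nest I/O curve has a nontrivial attracting
#' fixed point" to bracket the exact critical volatility `c*`, which the
#' count bound [critical_volatility()] bounds from above.
#'
#' @param lower,upper Initial bracket.
#' @param tol Bracket width at which to stop.
#' @param ... Passed to [nest_io_curve_analytic()].
#' @return Numeric vector `c(lower, upper)` bracketing `c*`.
#' @export
critical_volatility_bracket <- function(lower = 0.05, upper = 1, tol = 0.02,
                                        ...) {
  has_fp <- function(c) {
    curve <- nest_io_curve_analytic(c, r_in_grid = seq(0.02, 4,
                                                       length.out = 60), ...)
    fixed_points(curve)$r_star > 1e-3
  }
  if (has_fp(lower) || !has_fp(upper)) {
    abort("initial bracket does not straddle the critical volatility")
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (has_fp(mid)) upper <- mid else lower <- mid
  }
  c(lower = lower, upper = upper)
}

#' Quasi steady-state foraging rate as a function of volatility
#'
#' For each volatility, the attracting nontrivial fixed point of the
#' analytic nest I/O curve (0 if none): the predicted QSS foraging rate of
#' a single-volatility colony.
#'
#' @param c_grid Volatilities to evaluate.
#' @param r_in_grid Incoming-rate grid used for each curve.
#' @param ... Passed to [nest_io_curve_analytic()].
#' @return A tibble with columns `c` and `r_qss`.
#' @export
qss_vs_c <- function(c_grid, r_in_grid = seq(0.02, 5, length.out = 80),
                     ...) {
  if (any(c_grid <= 0)) abort("`c_grid` must be positive")
  r_qss <- vapply(c_grid, function(cc) {
    curve <- nest_io_curve_analytic(cc, r_in_grid = r_in_grid, ...)
    fixed_points(curve)$r_star
  }, numeric(1))
  tibble(c = c_grid, r_qss = r_qss)
}
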