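test_that("stimulus propagation is exact between and at jumps", {
  sp <- stimulus_params()
  expect_error(propagate_stimulus(event_sequence(1), sp, s0 = -0.1),
               "nonnegative")
  # single arrival at t = 0 from rest
  tr <- propagate_stimulus(event_sequence(0), sp)
  expect_equal(stimulus_at(tr, 0), 0.3)
  expect_equal(stimulus_at(tr, 1), 0.3 * exp(-1 / 0.41))
  # pure decay with no events
  tr2 <- propagate_stimulus(event_sequence(), sp, s0 = 1)
  expect_equal(stimulus_at(tr2, 0.41), exp(-1))
  expect_lt(stimulus_at(tr2, 10), 1e-10)
  # two simultaneous arrivals jump by 2k
  tr3 <- propagate_stimulus(event_sequence(c(0, 0)), sp)
  expect_equal(stimulus_at(tr3, 0), 0.6)
  # successive jumps compound the decayed value
  tr4 <- propagate_stimulus(event_sequence(c(0, 1)), sp)
  expect_equal(stimulus_at(tr4, 1), 0.3 * exp(-1 / 0.41) + 0.3)
})

test_that("stimulus trajectory agrees with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  sp <- stimulus_params()
  set.seed(21)
  ev <- generate_poisson_events(2, 20)
  tr <- propagate_stimulus(ev, sp, s0 = 0.1)
  # deSolve with its exact event mechanism as the oracle
  evdat <- data.frame(var = "s", time = unique(ev$time_s),
                      value = sp$k * as.numeric(table(ev$time_s)),
                      method = "add")
  tout <- sort(unique(c(seq(0, 20, by = 0.05), evdat$time)))
  out <- deSolve::ode(c(s = 0.1), tout,
                      function(t, y, p) list(-y / sp$tau),
                      NULL, events = list(data = evdat),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  # deSolve reports the pre-event value exactly at an event time, ours the
  # post-jump value; compare away from the jumps
  keep <- vapply(out[, "time"], function(t) {
    all(abs(t - evdat$time) > 1e-9)
  }, logical(1))
  ours <- stimulus_at(tr, out[keep, "time"])
  expect_lt(max(abs(ours - out[keep, "s"]) / pmax(out[keep, "s"], 1e-6)),
            1e-4)
})

test_that("Campbell moments and the Monte-Carlo time average agree", {
  sp <- stimulus_params()
  expect_error(stationary_moments(-1), "nonnegative")
  expect_equal(stationary_moments(0)$mean, 0)
  expect_equal(stationary_moments(0)$variance, 0)
  m <- stationary_moments(1, sp)
  expect_equal(m$mean, 0.123)
  expect_equal(m$variance, 0.3^2 * 0.41 / 2)
  # long propagation at r = 2 matches the Campbell mean
  set.seed(31)
  ev <- generate_poisson_events(2, 2000)
  tr <- propagate_stimulus(ev, sp)
  avg <- time_average_stimulus(tr, 50, 2000)
  # stationary sd 0.215, integral timescale ~tau: ~2400 effective samples
  expect_lt(abs(avg - 2 * 0.3 * 0.41), 0.03)
})

test_that("stationary density solves the level-crossing balance", {
  sp <- stimulus_params()
  expect_error(stationary_density(0), "positive")
  for (r in c(0.5, 1, 2, 5)) {
    d <- stationary_density(r, sp)
    h <- attr(d, "h")
    expect_true(all(d$density >= 0))
    # normalised to 1
    expect_lt(abs(max(d$cdf) - 1), 1e-6)
    # mean matches Campbell
    expect_lt(abs(sum(d$density * d$s) * h - r * 0.3 * 0.41), 1e-3)
    # nearly all mass below 10 * mean
    cdf_at <- approx(d$s, d$cdf, xout = min(10 * r * 0.3 * 0.41,
                                            max(d$s)), rule = 2)$y
    expect_gt(cdf_at, 0.999)
  }
})

test_that("density has the exact power-law form on the first interval", {
  # on (0, k) the balance gives p proportional to s^(r tau - 1)
  r <- 1 # r * tau = 0.41 < 1: decreasing, integrably divergent at 0+
  d <- stationary_density(r)
  sub <- d[d$s > 0.01 & d$s < 0.29, ]
  fit <- stats::lm(log(density) ~ log(s), data = sub)
  expect_equal(unname(stats::coef(fit)[2]), r * 0.41 - 1, tolerance = 1e-3)
  expect_true(all(diff(sub$density) < 0))
})

test_that("density is continuous at breakpoints and matches Monte Carlo", {
  sp <- stimulus_params()
  d <- stationary_density(2, sp)
  # continuity across s = k and s = 2k (compare adjacent grid cells)
  for (nk in c(0.3, 0.6)) {
    i <- which.min(abs(d$s - nk))
    expect_lt(abs(d$density[i + 1] - d$density[i - 1]),
              0.05 * max(d$density))
  }
  # KS distance between analytic CDF and stationary samples
  set.seed(41)
  x <- sample_stationary_stimulus(2e5, 2, sp)
  cdf_fun <- stats::approxfun(c(0, d$s), c(0, d$cdf), rule = 2)
  ks <- max(abs(cdf_fun(sort(x)) - (seq_along(x) - 0.5) / length(x)))
  expect_lt(ks, 0.01)
  # histogram fallback agrees with the analytic density (the narrow bins
  # carry ~150 counts each, so ~8% relative noise is expected)
  set.seed(42)
  dm <- stationary_density(2, sp, method = "mc", n_mc = 2e5)
  common <- d$s < 1
  expect_lt(mean(abs(dm$density[common] - d$density[common])), 0.12)
})
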