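test_that("bifurcation points follow the printed formula", {
  expect_error(fn_params(c = 25), "degenerate")
  # c near 0: b = a -/+ 1/3
  b0 <- bifurcation_points(fn_params(c = 1e-9))
  expect_equal(unname(b0), c(0.35 - 1 / 3, 0.35 + 1 / 3), tolerance = 1e-6)
  b5 <- bifurcation_points(fn_params(c = 5))
  expect_equal(unname(b5), c(0.13351, 0.56649), tolerance = 1e-4)
  # the arrival jump exceeds b1 throughout the working volatility range
  for (cc in c(0.01, 1, 3, 5)) {
    expect_gt(0.3, bifurcation_points(fn_params(c = cc))[["b1"]])
  }
  # band collapses onto a as c approaches 1/eps2
  bc <- bifurcation_points(fn_params(c = 19.999))
  expect_equal(unname(bc), c(0.35, 0.35), tolerance = 1e-4)
})

test_that("rest state solves the equilibrium and is stable below b1", {
  p <- fn_params(c = 1)
  rs <- rest_state(p, s = 0.35)
  expect_equal(rs$v, 0)
  expect_equal(rs$u, 0)
  expect_equal(rest_state(p, s = 0.35 + 1 / 3)$v, 1)
  # for s < b1 the linearisation has eigenvalues with negative real part
  b <- bifurcation_points(p)
  for (s in c(0.001, b[["b1"]] * 0.8)) {
    v <- rest_state(p, s)$v
    ev <- eigen(fn_jacobian(v, p))$values
    expect_true(all(Re(ev) < 0))
  }
  # inside the band the equilibrium is unstable
  v_mid <- rest_state(p, 0.35)$v
  expect_true(any(Re(eigen(fn_jacobian(v_mid, p))$values) > 0))
})

test_that("constant-stimulus regimes match the bifurcation structure", {
  p <- fn_params(c = 1)
  b <- bifurcation_points(p)
  # resting below b1, oscillating inside, saturated above b2
  n_spikes <- function(s) {
    nrow(simulate_fn(p, s, duration = 8, record_dt = 0)$spikes)
  }
  expect_equal(n_spikes(0), 0)
  expect_equal(n_spikes(0.8), 0)
  expect_gt(n_spikes(0.35), 5)
  # sweep with a tolerance band of 0.01 around the Hopf points
  for (s in c(0.05, b[["b1"]] - 0.01, b[["b1"]] + 0.015, 0.25, 0.5,
              b[["b2"]] - 0.015, b[["b2"]] + 0.01, 0.9)) {
    inside <- s > b[["b1"]] + 0.01 && s < b[["b2"]] - 0.01
    if (inside) expect_gt(n_spikes(s), 0) else expect_equal(n_spikes(s), 0)
  }
})

test_that("simulated period matches a fine-step oracle and spike spacing", {
  p <- fn_params(c = 1)
  t_coarse <- measure_fn_period(0.35, p)
  t_fine <- measure_fn_period(0.35, p, dt = 1e-4)
  expect_lt(abs(t_coarse - t_fine) / t_fine, 0.01)
  # spike count over a window equals duration / period +/- 1
  sim <- simulate_fn(p, 0.35, duration = 10, record_dt = 0)
  expect_lt(abs(nrow(sim$spikes) - 10 / t_fine), 1.5)
})

test_that("period approximation scales, brackets and converges", {
  p1 <- fn_params(c = 1)
  p2 <- fn_params(c = 2)
  expect_error(lc_period(0.01, p1), "band")
  # leading order is exactly inversely proportional to c
  expect_equal(lc_period(0.35, p1, correction = FALSE),
               2 * lc_period(0.35, p2, correction = FALSE))
  # symmetric about the band midpoint s = a
  expect_equal(lc_period(0.3, p1, correction = FALSE),
               lc_period(0.4, p1, correction = FALSE))
  # leading order underestimates the measured period across c
  for (cc in c(0.5, 1, 2, 5)) {
    pc <- fn_params(c = cc)
    expect_lt(lc_period(0.35, pc, correction = FALSE),
              measure_fn_period(0.35, pc))
  }
  # fold-delay correction brings it within ~3%
  for (cc in c(0.5, 1, 2, 5)) {
    pc <- fn_params(c = cc)
    expect_lt(abs(lc_period(0.35, pc) / measure_fn_period(0.35, pc) - 1),
              0.03)
  }
  # leading-order relative gap shrinks as eps2 decreases
  gaps <- vapply(c(0.05, 0.02, 0.01), function(e2) {
    pe <- fn_params(c = 1, eps2 = e2)
    t_num <- measure_fn_period(0.35, pe)
    (t_num - lc_period(0.35, pe, correction = FALSE)) / t_num
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("doubling the volatility roughly halves the minimum inter-spike interval", {
  min_isi <- function(cc) {
    sim <- simulate_fn(fn_params(c = cc), 0.35, duration = 6,
                       record_dt = 0)
    min(diff(sim$spikes$time_s))
  }
  expect_lt(abs(min_isi(2) / min_isi(1) - 0.5), 0.1 * 0.5 + 0.05)
})

test_that("open-loop response composes stimulus and FN dynamics", {
  # no input from rest: silence
  empty <- open_loop_response(fn_params(c = 1), event_sequence(),
                              duration = 5)
  expect_equal(nrow(empty), 0)
  # one isolated arrival elicits at least one departure for c in [0.3, 5]
  for (cc in c(0.3, 1, 3, 5)) {
    sp <- open_loop_response(fn_params(c = cc), event_sequence(0),
                             duration = 8)
    expect_gte(nrow(sp), 1)
  }
  # low volatility: exactly one departure per isolated arrival
  sp03 <- open_loop_response(fn_params(c = 0.3), event_sequence(0),
                             duration = 8)
  expect_equal(nrow(sp03), 1)
})

test_that("spike detection uses hysteresis and sub-step interpolation", {
  p <- fn_params(c = 1)
  sim <- simulate_fn(p, 0.35, duration = 6, record_dt = 0.001)
  st <- sim$spikes$time_s
  # spikes are strictly separated by the refractory drop below threshold
  expect_gt(min(diff(st)), 0.1)
  # interpolated spike times are interior to the trace steps: v just below
  # threshold at the sample preceding each spike
  before <- approx(sim$trace$time_s, sim$trace$v, xout = st - 0.002)$y
  expect_true(all(before < 0.76))
})
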