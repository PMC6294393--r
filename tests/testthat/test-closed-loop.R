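test_that("configuration validates its inputs", {
  expect_error(colony_config(c_u = 0, c_i = 1, N = 10, D = 5), "positive")
  expect_error(colony_config(c_u = 1, c_i = 1, N = 0, D = 5), ">= 1")
  expect_error(colony_config(c_u = 1, c_i = 1, N = 10, D = -1), "> 0")
})

test_that("closed loop conserves foragers and matches its event log", {
  cfg <- colony_config(c_u = 3, c_i = 0.9, N = 200, D = 2,
                       duration = 1800, seed = 3)
  rec <- suppressWarnings(run_closed_loop(cfg))
  # exact conservation at every sampled time
  with(rec$trace, expect_true(all(n_u + n_i + q == cfg$N)))
  expect_true(all(rec$trace$q >= 0 & rec$trace$q <= cfg$N))
  # every departure either returned or is still outside at the end
  n_out <- nrow(rec$lambda_out)
  n_ret <- sum(rec$lambda_in$source == "return")
  expect_equal(n_out, n_ret + length(rec$pending_returns))
  expect_equal(utils::tail(rec$trace$q, 1),
               cfg$N - rec$final$n_u - rec$final$n_i)
  # informed fraction stays in [0, 1] and ends high in a sustained run
  expect_true(all(rec$trace$x_i >= 0 & rec$trace$x_i <= 1))
  # kept spikes are a subset of the per-unit spike trains
  expect_lte(n_out, nrow(rec$lambda_u) + nrow(rec$lambda_i))
})

test_that("informed status is only gained, never lost", {
  cfg <- colony_config(c_u = 3, c_i = 0.9, N = 200, D = 2,
                       duration = 1800, seed = 3)
  rec <- suppressWarnings(run_closed_loop(cfg))
  # a drop in x_i can only come from an informed departure, not from
  # information loss: the informed pool balances returns against
  # informed departures exactly
  out_informed <- rec$lambda_out$time_s[rec$lambda_out$class == "informed"]
  ret <- rec$lambda_in$time_s[rec$lambda_in$source == "return"]
  # informed pool balance: n_i(t) = #returns(<=t) - #informed departures(<=t)
  ni_reconstructed <- findInterval(rec$trace$time_s, sort(ret)) -
    findInterval(rec$trace$time_s, sort(out_informed))
  expect_equal(rec$trace$n_i, ni_reconstructed)
  # and the uninformed pool only drains
  expect_true(all(diff(rec$trace$n_u) <= 0))
})

test_that("runs are reproducible from the seed", {
  cfg <- colony_config(c_u = 2, c_i = 2, N = 100, D = 2, duration = 900,
                       seed = 17)
  a <- suppressWarnings(run_closed_loop(cfg))
  b <- suppressWarnings(run_closed_loop(cfg))
  expect_identical(a$lambda_out$time_s, b$lambda_out$time_s)
  expect_identical(a$lambda_in$time_s, b$lambda_in$time_s)
})

test_that("pool exhaustion drops spikes with a warning", {
  cfg <- colony_config(c_u = 5, c_i = 5, N = 3, D = 10, duration = 600,
                       seed = 2, initial_rate = 0.05)
  expect_warning(rec <- run_closed_loop(cfg), "dropped")
  expect_gt(sum(rec$dropped), 0)
  expect_true(all(rec$trace$q <= 3))
})

test_that("QSS readout recovers known rates and the queueing identity", {
  # synthetic record with constant rates: exact recovery
  dur <- 7200
  times_in <- seq(0.5, dur, by = 2) # 0.5 ants/s
  times_out <- seq(1, dur, by = 2)
  fake <- list(lambda_in = tibble::tibble(time_s = times_in),
               lambda_out = tibble::tibble(time_s = times_out),
               trace = tibble::tibble(time_s = seq(0, dur), q = 42))
  q <- qss_estimate(fake, tail_fraction = 0.5)
  expect_equal(q$r_in_qss, 0.5, tolerance = 1e-6)
  expect_equal(q$r_out_qss, 0.5, tolerance = 1e-6)
  expect_equal(q$q_qss, 42)
  expect_error(qss_estimate(fake, tail_fraction = 0.01), "too short")
  # a sustained closed-loop run satisfies Q ~= r (per minute) * D
  cfg <- colony_config(c_u = 3, c_i = 0.9, N = 500, D = 5,
                       duration = 3 * 3600, seed = 1)
  rec <- suppressWarnings(run_closed_loop(cfg))
  qq <- qss_estimate(rec)
  expect_lt(qq$rate_gap_rel, 0.1)
  expect_lt(abs(qq$q_qss - qq$r_qss * 60 * cfg$D) / qq$q_qss, 0.1)
})

test_that("QSS is independent of the initialisation density", {
  qss_for <- function(rate, seed) {
    cfg <- colony_config(c_u = 2, c_i = 2, N = 1000, D = 2,
                         duration = 4500, seed = seed,
                         initial_rate = rate)
    qss_estimate(suppressWarnings(run_closed_loop(cfg)),
                 tail_fraction = 0.25)$r_qss
  }
  sparse <- qss_for(0.005, 23)
  dense <- qss_for(0.02, 24)
  expect_gt(sparse, 0.5)
  expect_lt(abs(sparse - dense) / ((sparse + dense) / 2), 0.2)
})

test_that("thinned two-unit blend reproduces the single-unit rate", {
  # with c_u = c_i the thinning probabilities sum to one, so the blended
  # outgoing rate must match one unthinned unit driven by the same
  # stimulus, whatever x_i is
  set.seed(77)
  ev <- generate_poisson_events(1.5, 600)
  tr <- propagate_stimulus(ev, default_stim)
  p <- fn_at(2)
  one <- simulate_fn(p, tr, duration = 600, record_dt = 0)
  spikes_a <- simulate_fn(p, tr, duration = 600, record_dt = 0)$spikes
  spikes_b <- simulate_fn(p, tr, duration = 600, record_dt = 0)$spikes
  x_i <- 0.4
  kept <- c(spikes_a$time_s[runif(nrow(spikes_a)) < 1 - x_i],
            spikes_b$time_s[runif(nrow(spikes_b)) < x_i])
  n_expect <- nrow(one$spikes)
  # binomial thinning noise: sd ~ sqrt(n p (1-p)) per train
  expect_lt(abs(length(kept) - n_expect), 3 * sqrt(n_expect))
})

test_that("closed-loop QSS agrees with the open-loop fixed-point analysis", {
  # two-stage cross-validation at c_u = c_i = 2: the closed loop should
  # reproduce the diagonal crossing of the *simulated* open-loop curve
  # closely, and the analytic curve's crossing within the accuracy of the
  # ergodic approximation
  cl <- vapply(1:2, function(s) {
    cfg <- colony_config(c_u = 2, c_i = 2, N = 2000, D = 5,
                         duration = 2 * 3600, seed = 100 + s)
    qss_estimate(suppressWarnings(run_closed_loop(cfg)),
                 tail_fraction = 0.25)$r_qss
  }, numeric(1))
  set.seed(55)
  grid <- seq(1.5, 4, by = 0.5)
  sim_curve <- nest_io_curve_simulated(2, r_in_grid = grid, trials = 6)
  fp_sim <- uniroot(function(r) {
    approx(sim_curve$r_in, sim_curve$r_out, xout = r)$y - r
  }, range(grid))$root
  an_curve <- nest_io_curve_analytic(2, r_in_grid = seq(0.1, 5,
                                                        length.out = 40))
  fp_an <- fixed_points(an_curve)$r_star
  expect_lt(abs(mean(cl) - fp_sim) / fp_sim, 0.15)
  expect_lt(abs(mean(cl) - fp_an) / fp_an, 0.30)
})
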