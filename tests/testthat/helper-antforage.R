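# Shared fixtures and small oracles for the test suite.

default_stim <- stimulus_params() # k = 0.3, tau = 0.41

fn_at <- function(c) fn_params(c = c)

# Jacobian of the FN vector field at a state (independent derivation used
# to check stability claims)
fn_jacobian <- function(v, params) {
  with(params, matrix(c(
    (1 - v^2) / (eps1 * eps2), -c / (eps1 * eps2),
    1 / eps1, -c / eps1), nrow = 2, byrow = TRUE))
}

# brute-force cobweb iteration on a curve's interpolant
cobweb_limit <- function(curve, r0, n = 400) {
  g <- function(r) approx(curve$r_in, curve$r_out, xout = r,
                          yleft = 0, rule = 2)$y
  r <- r0
  for (i in seq_len(n)) r <- g(r)
  r
}

# time-averaged value of a stimulus trajectory on a regular grid
time_average_stimulus <- function(traj, t_from, t_to, by = 0.05) {
  mean(stimulus_at(traj, seq(t_from, t_to, by = by)))
}
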