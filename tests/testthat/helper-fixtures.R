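# Shared fixtures: small grids and covariance models reused across tests.
# Everything is built in code; sizes are kept small so the full suite stays
# fast while the statistical checks retain power.

grid_100ms <- function() grid_1d(200, 0.5)   # the task grid: 100 ms at 2 kHz
grid_small <- function() grid_1d(40, 1)      # 40 ms at 1 kHz, d = 40

sensilla_compatible <- function() {
  build_sensilla_cov(grid_100ms(), f_lo = 10, f_hi = 60, gamma = 50)
}

# Monte-Carlo variance of w^T x with its standard error, for Theorem-1 checks
mc_projection_var <- function(cov, x, m, seed) {
  W <- sample_weights(cov, m, seed = seed)$W
  v <- drop(W %*% x)
  list(var = stats::var(v), se = stats::var(v) * sqrt(2 / (m - 1)))
}
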