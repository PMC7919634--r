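# Shared fixtures, built in code at test time.

# Y tracks X with a pure implanted delay plus additive Gaussian noise.
make_delayed_pair <- function(d = 10, n = 6000, noise_sd = 0.2, a1 = 2,
                              seed = 101) {
  ts <- generate_target(signal_config(a1 = a1, n_frames = n + 600, seed = seed))
  x <- ts$positions
  y <- c(rep(0, d), x[seq_len(length(x) - d)]) +
    withr::with_seed(seed + 1, stats::rnorm(length(x), sd = noise_sd))
  trajectory_pair(x, y)
}

# Stationary autocovariance function of the AR(2) target at unit marginal
# variance, for closed-form Gaussian oracles.
ar2_autocov <- function(config, max_lag) {
  phi <- ar_coefficients(config)
  stats::ARMAacf(ar = phi, lag.max = max_lag)  # autocorrelation = autocov at unit var
}

# Exact Gaussian conditional MI I(y; x | z) in bits from a joint covariance
# matrix and index sets: the closed-form oracle the copula estimator is
# checked against.
gaussian_cmi_bits <- function(S, iy, ix, iz) {
  ld <- function(ii) as.numeric(determinant(S[ii, ii, drop = FALSE])$modulus)
  if (length(iz) == 0)
    return(0.5 * (ld(iy) + ld(ix) - ld(c(iy, ix))) / log(2))
  0.5 * (ld(c(iy, iz)) + ld(c(ix, iz)) - ld(iz) - ld(c(iy, ix, iz))) / log(2)
}

# Exact (closed-form Gaussian) transfer-entropy value of the pure-shift
# channel Y_t = X_{t-true_d} + noise at candidate delay d, and the argmax over
# a delay range: the independent oracle for peak-latency behaviour.
shift_channel_te <- function(config, true_d, noise_sd, d) {
  g <- ar2_autocov(config, 2 * (true_d + d) + 4)
  gam <- function(l) g[abs(l) + 1]
  lags <- c(0, d, d + 1, d, d + 1, 1)  # Y_t, X block, Y-history block
  is_y <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  S <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    li <- lags[i] + if (is_y[i]) true_d else 0
    lj <- lags[j] + if (is_y[j]) true_d else 0
    S[i, j] <- gam(li - lj) +
      if (is_y[i] && is_y[j] && lags[i] == lags[j]) noise_sd^2 else 0
  }
  gaussian_cmi_bits(S, 1, 2:3, 4:6)
}

shift_channel_peak <- function(config, true_d, noise_sd, d_min, d_max) {
  dd <- d_min:d_max
  dd[which.max(vapply(dd, function(d)
    shift_channel_te(config, true_d, noise_sd, d), numeric(1)))]
}

# The acceptance sweeps are expensive; compute them once per test session.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function() {
  if (is.null(.acceptance_cache$sweep))
    .acceptance_cache$sweep <- run_predictability_sweep(sweep_config())
  .acceptance_cache$sweep
}

acceptance_vmd_sweep <- function() {
  if (is.null(.acceptance_cache$vmd))
    .acceptance_cache$vmd <- run_vmd_sweep(sweep_config())
  .acceptance_cache$vmd
}
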