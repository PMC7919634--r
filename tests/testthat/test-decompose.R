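test_that("feedback information vanishes for perfect zero-lag prediction and independent tracking", {
  ts <- generate_target(signal_config(a1 = 2, n_frames = 6500, seed = 31))
  x <- ts$positions

  # Y = X: the conditioning set contains the target's past through Y's copies
  pair_id <- trajectory_pair(x, x + withr::with_seed(1, rnorm(length(x), sd = 1e-6)))
  ifb_id <- compute_ifb(pair_id, vmd = 12)
  # Y independent of X
  pair_ind <- trajectory_pair(x, withr::with_seed(2, rnorm(length(x))))
  ifb_ind <- compute_ifb(pair_ind, vmd = 12)
  # null scale from circularly shifted targets
  null <- vapply(1:15, function(s) withr::with_seed(s, {
    n <- length(x)
    k <- sample(500:(n - 500), 1)
    compute_ifb(trajectory_pair(x[c((k + 1):n, 1:k)], pair_id$tracking), 12)
  }), numeric(1))
  thr <- 3 * sd(null) + abs(mean(null))
  expect_lt(abs(ifb_id), thr + 0.02)
  expect_lt(abs(ifb_ind), thr + 0.02)

  # and Itotal for independent tracking is ~ 0 too
  expect_lt(abs(compute_itotal(pair_ind, vmd = 12)), 0.02)
})

test_that("a pure delayed feedback channel matches the exact Gaussian conditional MI", {
  d <- 10; noise_sd <- 0.5
  cfg <- signal_config(a1 = 2, n_frames = 21000, burn_in = 1000, seed = 55)
  pair <- local({
    x <- generate_target(cfg)$positions
    y <- c(rep(0, d), x[seq_len(length(x) - d)]) +
      withr::with_seed(56, rnorm(length(x), sd = noise_sd))
    trajectory_pair(x, y)
  })

  # closed-form joint covariance of (Y_t, X_{t-d}, X_{t-d-1},
  #                                  Y_{t-d}, Y_{t-d-1}, Y_{t-1})
  g <- ar2_autocov(cfg, 3 * d + 2)           # unit-variance autocovariance
  gam <- function(l) g[abs(l) + 1]
  # variable lags relative to t: Y lags have Y_s = X_{s-d} + eps_s
  ylag <- c(0, d, d + 1, 1)                  # Y_t, Y_{t-d}, Y_{t-d-1}, Y_{t-1}
  xlag <- c(d, d + 1)                        # X_{t-d}, X_{t-d-1}
  idx_y <- 1; idx_x <- 2:3; idx_z <- 4:6
  lags <- c(0, xlag, ylag[-1])               # order: Y_t, X block, Z block
  is_y <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  S <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    li <- lags[i] + if (is_y[i]) d else 0    # effective X-lag of each variable
    lj <- lags[j] + if (is_y[j]) d else 0
    S[i, j] <- gam(li - lj) +
      if (is_y[i] && is_y[j] && lags[i] == lags[j]) noise_sd^2 else 0
  }
  truth <- gaussian_cmi_bits(S, idx_y, idx_x, idx_z)

  est <- compute_ifb(pair, vmd = d)
  expect_gt(est, 0.1)                        # clearly informative channel
  expect_equal(est, truth, tolerance = 0.06)

  # total >= feedback on the same channel, and offsets leave Itotal unchanged
  itot <- compute_itotal(pair, vmd = d)
  expect_gt(itot, est - 0.02)
  shifted <- trajectory_pair(pair$target, pair$tracking + 7)
  expect_equal(compute_itotal(shifted, vmd = d), itot)
})

test_that("the decomposition identity and rate conversion are exact", {
  pair <- make_delayed_pair(d = 10, n = 4000)
  expect_equal(compute_iff(pair, 10),
               compute_itotal(pair, 10) - compute_ifb(pair, 10))
  dec <- decompose_tracking(pair, vmd = 10)
  expect_identical(dec$iff, dec$itotal - dec$ifb)
  expect_identical(dec$ifb_per_second, dec$ifb * 60)
  expect_equal(rate_per_second(0, 60), 0)
  expect_equal(rate_per_second(0.05, 60), 3)
  expect_equal(rate_per_second(0.2, 60), 12)
  expect_named(coef(dec), c("ifb", "iff", "itotal"))
})

test_that("the transfer-entropy curve peaks where the exact Gaussian curve peaks", {
  cfg <- signal_config(a1 = 2, n_frames = 1000)
  # oracle: closed-form CMI of the shift channel over the scanned range
  oracle_peak <- shift_channel_peak(cfg, true_d = 10, noise_sd = 0.1, 2, 30)
  pair <- make_delayed_pair(d = 10, n = 6000, noise_sd = 0.1)
  curve <- te_latency_curve(pair, 2, 30, n_surrogates = 30)
  expect_equal(curve$peak_delay, oracle_peak)
  expect_false(curve$low_confidence)
  expect_true(all(is.finite(curve$te_values)))
  expect_true(curve$peak_delay %in% curve$delays)

  # the peak follows the implanted delay one-for-one
  pair14 <- make_delayed_pair(d = 14, n = 6000, noise_sd = 0.1)
  curve14 <- te_latency_curve(pair14, 2, 30, n_surrogates = 0)
  expect_equal(curve14$peak_delay - curve$peak_delay, 4)

  # independent tracking: flat curve, flagged low-confidence
  ts <- generate_target(signal_config(a1 = 2, n_frames = 4500, seed = 61))
  ind <- trajectory_pair(ts$positions,
                         withr::with_seed(3, rnorm(length(ts$positions))))
  flat <- te_latency_curve(ind, 2, 20, n_surrogates = 30)
  expect_true(flat$low_confidence)
  expect_lt(max(abs(flat$te_values)), 0.05)

  expect_error(te_latency_curve(pair, 10, 5), "d_min < d_max")
})

test_that("VMD estimation averages per-trial peak latencies", {
  cfg <- signal_config(a1 = 2, n_frames = 1000)
  peak14 <- shift_channel_peak(cfg, 14, 0.1, 2, 25)   # exact-curve argmax
  peak16 <- shift_channel_peak(cfg, 16, 0.1, 2, 25)
  trials <- lapply(c(301, 302, 303), function(s)
    make_delayed_pair(d = 14, n = 5000, noise_sd = 0.1, seed = s))
  est <- estimate_vmd(trials, 2, 25, n_surrogates = 20)
  expect_equal(est$vmd, peak14)
  expect_equal(est$sd, 0)
  expect_equal(est$n_trials, 3)

  # mixed implanted delays average arithmetically
  mixed <- list(make_delayed_pair(d = 14, n = 5000, noise_sd = 0.1, seed = 311),
                make_delayed_pair(d = 16, n = 5000, noise_sd = 0.1, seed = 312))
  expect_equal(estimate_vmd(mixed, 2, 25, n_surrogates = 20)$vmd,
               mean(c(peak14, peak16)))

  # single trial: dispersion undefined
  single <- estimate_vmd(trials[[1]], 2, 25, n_surrogates = 20)
  expect_true(is.na(single$sd))

  # all-noise trials carry no recoverable delay
  ts <- generate_target(signal_config(a1 = 2, n_frames = 4500, seed = 71))
  noise_trial <- trajectory_pair(ts$positions,
                                 withr::with_seed(4, rnorm(length(ts$positions))))
  expect_error(estimate_vmd(list(noise_trial), 2, 20, n_surrogates = 30),
               "low-confidence")
})

test_that("performance lag finds the cross-correlation peak", {
  ts <- generate_target(signal_config(a1 = 1, n_frames = 3000, seed = 81))
  x <- ts$positions
  y5 <- c(rep(0, 5), x[seq_len(length(x) - 5)])
  expect_equal(performance_lag(trajectory_pair(x, y5)), 5)
  expect_equal(performance_lag(trajectory_pair(x, x)), 0)
  expect_error(performance_lag(trajectory_pair(x, rep(1, length(x)))),
               "degenerate|constant")
  expect_error(performance_lag(trajectory_pair(x, y5), max_lag = 2000), "length/4")
})
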