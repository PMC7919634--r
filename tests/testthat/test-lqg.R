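test_that("plant assembly follows the documented block layout", {
  cfg <- signal_config(a1 = 2, n_frames = 1000)
  plant <- build_plant(cfg, visual_delay = 5, motor_delay = 3)
  n <- nrow(plant$A)
  expect_equal(n, 2 + 3 + 2 + 5 + 1)
  expect_equal(dim(plant$B), c(n, 1))
  expect_equal(dim(plant$C), c(2, n))
  expect_equal(effective_vmd(plant), 5 + 3 + 1)

  # joystick core rows [0,1] and the printed spring-mass coefficients
  expect_equal(plant$A[1, 1:2], c(0, 1))
  expect_equal(plant$A[2, 1:2], c(-0.01, 0.81))

  # motor delay line is a shift register: a control injected via B reaches
  # the line's output tap after (m-1) steps and the joystick the step after
  m <- 3
  Apow <- diag(n)
  for (i in seq_len(m - 1)) Apow <- Apow %*% plant$A
  expect_equal((Apow %*% plant$B)[plant$idx$motor[m], 1], 1)
  expect_equal((Apow %*% plant$A %*% plant$B)[plant$idx$j2, 1], 1)

  # visual delay line delivers x_{t-v} at the observed tap
  v <- 5
  z <- numeric(n); z[plant$idx$x2] <- 1  # unit impulse on the target state
  plant0 <- build_plant(list(phi = c(0, 0), sd = 1), visual_delay = v,
                        motor_delay = 3)  # freeze target dynamics for purity
  zz <- z
  for (i in seq_len(v)) zz <- as.numeric(plant0$A %*% zz)
  expect_equal(zz[plant0$idx$visual[v]], 1)

  # zero-delay plant reduces to the bare cores
  p0 <- build_plant(cfg, visual_delay = 0, motor_delay = 0)
  expect_equal(nrow(p0$A), 5)
  expect_equal(p0$A[2, 1:2], c(-0.01, 0.81))
  expect_equal(p0$B[2, 1], 1)

  # process noise restricted to the noise-driven coordinates is nonsingular
  idx <- plant$idx$noise_driven
  expect_gt(det(plant$Q_proc[idx, idx]), 0)
})

test_that("the Kalman filter is exact in the noiseless limit and symmetric under noise", {
  A <- rbind(c(0.9, 0.2), c(-0.1, 0.8))
  C <- diag(2)
  sys0 <- list(A = A, B = matrix(0, 2, 1), C = C,
               Q_proc = matrix(0, 2, 2), R_obs = matrix(0, 2, 2))
  s_true <- c(1, -0.5)
  st <- kalman_state(s_true, matrix(0, 2, 2))
  for (i in 1:20) {
    s_true <- as.numeric(A %*% s_true)
    st <- kalman_step(st, s_true, sys0)
    expect_equal(st$mean, s_true, tolerance = 1e-12)
  }

  # with noise, Joseph-form updates keep the covariance symmetric PSD
  sys <- list(A = A, B = matrix(0, 2, 1), C = C,
              Q_proc = diag(0.1, 2), R_obs = diag(0.5, 2))
  st <- kalman_state(c(0, 0), diag(1, 2))
  obs <- withr::with_seed(5, matrix(rnorm(2000), ncol = 2))
  for (i in 1:1000) st <- kalman_step(st, obs[i, ], sys)
  expect_lt(max(abs(st$covariance - t(st$covariance))), 1e-10)
  expect_true(all(eigen(st$covariance, only.values = TRUE)$values > -1e-12))
})

test_that("steady-state covariance solves the scalar Riccati equation", {
  a <- 0.95; cc <- 1.3; q <- 0.4; r <- 2.0
  sys <- list(A = matrix(a), B = matrix(0), C = matrix(cc),
              Q_proc = matrix(q), R_obs = matrix(r))
  ss <- steady_state_kalman(sys)
  # closed-form positive root of c^2 p^2 + p(r - a^2 r - q c^2) - q r = 0
  bq <- r - a^2 * r - q * cc^2
  root <- (-bq + sqrt(bq^2 + 4 * cc^2 * q * r)) / (2 * cc^2)
  expect_equal(ss$prior[1, 1], root, tolerance = 1e-8)
})

test_that("receding-horizon control matches the one-step and infinite-horizon solutions", {
  cfg <- signal_config(a1 = 2, n_frames = 1000)
  plant <- build_plant(cfg, visual_delay = 3, motor_delay = 1, horizon = 6)
  expect_equal(mpc_control(numeric(nrow(plant$A)), plant), 0)

  # horizon 1: u = -(B'QB + R)^{-1} B'QA s
  A <- rbind(c(1, 0.1), c(-0.3, 0.9)); B <- matrix(c(0, 1))
  Q <- diag(c(2, 1)); R <- matrix(0.5)
  sys <- list(A = A, B = B, Q_cost = Q, R_cost = R, horizon = 1L)
  g1 <- mpc_gain(sys)
  oracle1 <- solve(t(B) %*% Q %*% B + R, t(B) %*% Q %*% A)
  expect_equal(as.numeric(g1), as.numeric(oracle1), tolerance = 1e-12)

  # long horizon approaches the LQR gain from the discrete algebraic
  # Riccati equation (independent value-iteration oracle)
  P <- Q
  for (i in 1:5000) {
    Pn <- Q + t(A) %*% (P - P %*% B %*% solve(R + t(B) %*% P %*% B) %*%
                          t(B) %*% P) %*% A
    if (max(abs(Pn - P)) < 1e-13) { P <- Pn; break }
    P <- Pn
  }
  k_lqr <- solve(R + t(B) %*% P %*% B, t(B) %*% P %*% A)
  g_long <- mpc_gain(list(A = A, B = B, Q_cost = Q, R_cost = R, horizon = 80L))
  expect_equal(as.numeric(g_long), as.numeric(k_lqr), tolerance = 1e-6)
})

test_that("ground-truth information terms obey their closed forms and limits", {
  # scalar feedback information: 0.5*log2(1 + c^2 sigma^2 / r)
  sysf <- list(C = matrix(1.5), R_obs = matrix(0.8))
  sig2 <- 0.6
  expect_equal(ground_truth_tfb(matrix(sig2), sysf),
               0.5 * log2(1 + 1.5^2 * sig2 / 0.8))
  # uninformative observations and nothing-to-learn limits
  expect_lt(ground_truth_tfb(matrix(sig2), list(C = matrix(1.5), R_obs = matrix(1e9))),
            1e-6)
  expect_lt(ground_truth_tfb(matrix(1e-12), sysf), 1e-6)
  expect_error(ground_truth_tfb(matrix(sig2), list(C = matrix(1), R_obs = matrix(0))),
               "singular")

  # feedforward: 0.5*log2(|Sigma|/|Q|) on the noise-driven coordinates
  cfg <- signal_config(a1 = 2, n_frames = 1000)
  plant <- build_plant(cfg, visual_delay = 2, motor_delay = 1)
  idx <- plant$idx$noise_driven
  Qs <- plant$Q_proc[idx, idx]
  expect_equal(ground_truth_tff(Qs, plant), 0)        # Sigma = Q -> 0 bits
  expect_equal(ground_truth_tff(4 * Qs, plant),
               0.5 * log2(det(4 * Qs) / det(Qs)))
  expect_gt(ground_truth_tff(4 * Qs, plant), ground_truth_tff(2 * Qs, plant))
})

test_that("closed-loop simulation is deterministic, stable and information-consistent", {
  cfg <- signal_config(a1 = 2, n_frames = 5700, seed = 15)
  tgt <- generate_target(cfg)
  plant <- build_plant(cfg)
  r1 <- simulate_tracking(plant, tgt, seed = 4)
  r2 <- simulate_tracking(plant, tgt, seed = 4)
  expect_identical(r1$pair$tracking, r2$pair$tracking)
  expect_true(all(is.finite(r1$pair$tracking)))
  expect_true(all(abs(r1$pair$tracking) < 100))  # bounded, unit-scale target
  expect_true(all(is.finite(r1$ground_truth)))
  expect_gte(r1$ground_truth["tfb"], 0)
  expect_gte(r1$ground_truth["tff"], 0)

  # the copula estimate cannot exceed the model-internal ground truth
  ifb <- compute_ifb(r1$pair, effective_vmd(plant))
  null_sd <- sd(vapply(1:10, function(s) withr::with_seed(s, {
    n <- length(r1$pair$target)
    k <- sample(500:(n - 500), 1)
    compute_ifb(trajectory_pair(r1$pair$target[c((k + 1):n, 1:k)],
                                r1$pair$tracking), effective_vmd(plant))
  }), numeric(1)))
  expect_lt(ifb, r1$ground_truth["tfb"] + 3 * max(null_sd, 0.01))

  # predictable target: prediction compensates part of the delay
  cfg_p <- signal_config(a1 = 1, n_frames = 5700, seed = 16)
  run_p <- simulate_tracking(build_plant(cfg_p), generate_target(cfg_p), seed = 5)
  expect_lt(performance_lag(run_p$pair), run_p$true_vmd)

  # less predictable target: lag moves closer to the visuomotor delay
  cfg_u <- signal_config(a1 = 6, n_frames = 5700, seed = 17)
  run_u <- simulate_tracking(build_plant(cfg_u), generate_target(cfg_u), seed = 6)
  expect_gt(performance_lag(run_u$pair), performance_lag(run_p$pair))

  # simulate() S3 method wraps simulate_tracking
  r3 <- simulate(plant, target = tgt, seed = 4)
  expect_identical(r3$pair$tracking, r1$pair$tracking)
})
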