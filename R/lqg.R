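#' Build the delay-augmented tracking plant
#'
#' Assembles the linear state-space model of the visuomotor tracking task.
#' The state vector stacks, in order:
#' \enumerate{
#'   \item the joystick second-order (spring-mass) pair \eqn{(j_{t-1}, j_t)}
#'     in companion form, with dynamic row coefficients
#'     \code{spring_mass = c(-0.01, 0.81)} so that
#'     \eqn{j_t = 0.81 j_{t-1} - 0.01 j_{t-2} + u};
#'   \item a motor delay line of length \code{motor_delay} (shift register
#'     the control command traverses before reaching the joystick);
#'   \item the target AR(2) pair \eqn{(x_{t-1}, x_t)} in companion form;
#'   \item a visual delay line of length \code{visual_delay} whose last tap
#'     \eqn{x_{t-visual}} is what the observer sees;
#'   \item one error state \eqn{e_t = x_t - j_t} (plus a small independent
#'     representation noise), the coordinate the controller regulates.
#' }
#' State dimension is therefore \code{2 + motor_delay + 2 + visual_delay + 1}.
#' The observation exposes the current joystick position (efference copy /
#' proprioception) and the visually delayed target position, both corrupted
#' by observation noise. The effective visuomotor delay of the closed loop is
#' \code{visual_delay + motor_delay + 1} (one frame of control-to-plant
#' latency), plus the smearing of the joystick dynamics.
#'
#' @param target A [signal_config()] (resonator form) describing the target
#'   dynamics the model knows, or a list with elements \code{phi} (AR(2)
#'   coefficients) and \code{sd} (innovation sd).
#' @param visual_delay,motor_delay Delays in frames (>= 0).
#' @param horizon Receding-horizon length N for the controller (must exceed
#'   \code{motor_delay + 1} for the control to influence the cost).
#' @param spring_mass Joystick dynamic row \code{c(lag-2 coef, lag-1 coef)}.
#' @param q_error State cost on the error coordinate (all other states
#'   uncosted).
#' @param r_control Quadratic control cost.
#' @param sigma_motor Joystick process-noise sd.
#' @param sigma_err Error-state representation-noise sd (keeps the process
#'   noise nonsingular on the noise-driven subspace).
#' @param obs_sd Observation-noise sd (both channels).
#' @return Object of class \code{"plant_model"} with matrices \code{A},
#'   \code{B}, \code{C}, \code{Q_proc}, \code{R_obs}, \code{Q_cost},
#'   \code{R_cost}, the precomputed receding-horizon gain, index bookkeeping
#'   and \code{effective_vmd}.
#' @export
build_plant <- function(target, visual_delay = 12, motor_delay = 3,
                        horizon = 10, spring_mass = c(-0.01, 0.81),
                        q_error = 1, r_control = 0.01,
                        sigma_motor = 0.02, sigma_err = 0.01, obs_sd = 0.1) {
  if (inherits(target, "signal_config")) {
    if (target$form != "resonator")
      stop("plant target model requires the stable resonator form")
    phi <- ar_coefficients(target)
    sigma_target <- sd_innovation(target)
  } else {
    phi <- target$phi; sigma_target <- target$sd
  }
  if (length(phi) != 2L) stop("target state space must be order 2")
  v <- as.integer(visual_delay); m <- as.integer(motor_delay)
  if (v < 0 || m < 0) stop("delays must be >= 0")
  if (horizon < 1) stop("`horizon` must be >= 1")
  if (length(spring_mass) != 2L) stop("`spring_mass` must have 2 coefficients")
  if (horizon <= m + 1)
    warning("horizon (", horizon, ") <= motor_delay + 1: control cannot ",
            "influence the cost; increase `horizon`")

  n <- 2L + m + 2L + v + 1L
  idx <- list(
    j1 = 1L, j2 = 2L,
    motor = if (m > 0) 2L + seq_len(m) else integer(0),
    x1 = 2L + m + 1L, x2 = 2L + m + 2L,
    visual = if (v > 0) 2L + m + 2L + seq_len(v) else integer(0),
    e = n
  )
  idx$noise_driven <- c(idx$j2, idx$x2, idx$e)
  u_src <- if (m > 0) idx$motor[m] else NA_integer_  # where control enters j

  A <- matrix(0, n, n); B <- matrix(0, n, 1)
  A[idx$j1, idx$j2] <- 1
  A[idx$j2, c(idx$j1, idx$j2)] <- spring_mass
  if (m > 0) {
    A[idx$j2, u_src] <- 1
    B[idx$motor[1], 1] <- 1
    if (m > 1) for (i in 2:m) A[idx$motor[i], idx$motor[i - 1]] <- 1
  } else {
    B[idx$j2, 1] <- 1
  }
  A[idx$x1, idx$x2] <- 1
  A[idx$x2, c(idx$x1, idx$x2)] <- c(phi[2], phi[1])
  if (v > 0) {
    A[idx$visual[1], idx$x2] <- 1
    if (v > 1) for (i in 2:v) A[idx$visual[i], idx$visual[i - 1]] <- 1
  }
  # error row: e_t = x_t - j_t (+ representation noise)
  A[idx$e, ] <- A[idx$x2, ] - A[idx$j2, ]
  B[idx$e, 1] <- -B[idx$j2, 1]

  C <- matrix(0, 2, n)
  C[1, idx$j2] <- 1
  C[2, if (v > 0) idx$visual[v] else idx$x2] <- 1

  # process noise loading: target innovation, motor noise, error representation
  L <- matrix(0, n, 3)
  L[idx$x2, 1] <- 1; L[idx$e, 1] <- 1
  L[idx$j2, 2] <- 1; L[idx$e, 2] <- -1
  L[idx$e, 3] <- 1
  sigmas <- c(target = sigma_target, motor = sigma_motor, err = sigma_err)
  Q_proc <- L %*% diag(sigmas^2) %*% t(L)

  Q_cost <- matrix(0, n, n); Q_cost[idx$e, idx$e] <- q_error
  R_cost <- matrix(r_control, 1, 1)
  R_obs <- diag(obs_sd^2, 2)

  plant <- structure(
    list(A = A, B = B, C = C, Q_proc = Q_proc, R_obs = R_obs,
         Q_cost = Q_cost, R_cost = R_cost, horizon = as.integer(horizon),
         visual_delay = v, motor_delay = m, idx = idx, L = L, sigmas = sigmas,
         phi = phi, spring_mass = spring_mass,
         effective_vmd = v + m + 1L),
    class = "plant_model"
  )
  plant$mpc_gain <- mpc_gain(plant)
  plant
}

#' @export
print.plant_model <- function(x, ...) {
  cat("LQG tracking plant\n")
  cat(sprintf("  state dim %d = 2 (joystick) + %d (motor line) + 2 (target) + %d (visual line) + 1 (error)\n",
              nrow(x$A), x$motor_delay, x$visual_delay))
  cat(sprintf("  effective VMD %d frames; horizon %d; target phi = (%.4f, %.4f), innovation sd %.4g\n",
              x$effective_vmd, x$horizon, x$phi[1], x$phi[2], x$sigmas["target"]))
  invisible(x)
}

#' Effective visuomotor delay of a plant
#'
#' \code{visual_delay + motor_delay + 1}: the number of frames between a
#' target displacement and the first frame at which the control reaction can
#' move the joystick (the extra frame is the control-to-plant latency; the
#' joystick dynamics add further smearing but no pure delay).
#'
#' @param plant A \code{plant_model}.
#' @return Delay in frames.
#' @export
effective_vmd <- function(plant) plant$effective_vmd

#' Receding-horizon (batch) control gain
#'
#' Solves the finite-horizon quadratic problem in batch form. Stacking the
#' predicted states \eqn{s_{t+1..t+N}} as \eqn{\hat A s_t + \bar C u_{0..N-1}}
#' (\eqn{\hat A} the stacked powers of A, \eqn{\bar C} the block lower
#' triangular matrix of \eqn{A^{i-j}B}), the minimizer of the quadratic cost
#' is \eqn{u^* = -(\bar C^T \bar Q \bar C + \bar R)^{-1}\bar C^T \bar Q \hat A\, s_t}
#' with \eqn{\bar Q, \bar R} block-diagonal repetitions of the state and
#' control costs. Only the first control of the sequence is applied
#' (receding horizon), so the returned gain is that first row block.
#'
#' @param plant A \code{plant_model}.
#' @return 1 x n gain matrix \code{K} such that \code{u = -K s}.
#' @export
mpc_gain <- function(plant) {
  A <- plant$A; B <- plant$B; N <- plant$horizon
  n <- nrow(A)
  Ahat <- matrix(0, n * N, n)
  Cbar <- matrix(0, n * N, N)
  Ap <- diag(n)
  pows <- vector("list", N + 1); pows[[1]] <- Ap
  for (i in seq_len(N)) pows[[i + 1]] <- pows[[i]] %*% A
  for (i in seq_len(N)) {
    rows <- (i - 1) * n + seq_len(n)
    Ahat[rows, ] <- pows[[i + 1]]
    for (j in seq_len(i)) Cbar[rows, j] <- pows[[i - j + 1]] %*% B
  }
  QC <- do.call(rbind, lapply(seq_len(N), function(i) {
    rows <- (i - 1) * n + seq_len(n)
    plant$Q_cost %*% Cbar[rows, , drop = FALSE]
  }))
  # Qbar is block-diagonal, so Qbar %*% Cbar applies Q_cost blockwise
  H <- t(Cbar) %*% QC + diag(as.numeric(plant$R_cost), N)
  Fmat <- t(QC) %*% Ahat
  Hi <- tryCatch(solve(H, Fmat), error = function(e)
    stop("horizon cost matrix H is not invertible; increase `r_control`"))
  Hi[1, , drop = FALSE]
}

#' Receding-horizon control from a state estimate
#'
#' Applies the precomputed batch gain: \code{u = -K s}. Linear in the state,
#' zero at the origin.
#'
#' @param state_mean State estimate vector (length n).
#' @param plant A \code{plant_model}.
#' @return Scalar control.
#' @export
mpc_control <- function(state_mean, plant) {
  -as.numeric(plant$mpc_gain %*% state_mean)
}

#' Create a Kalman state
#'
#' @param mean State estimate vector.
#' @param covariance Symmetric PSD covariance matrix.
#' @param prior_covariance Optional pre-update covariance (kept for
#'   information accounting).
#' @return Object of class \code{"kalman_state"}.
#' @export
kalman_state <- function(mean, covariance, prior_covariance = NULL) {
  covariance <- (covariance + t(covariance)) / 2
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 prior_covariance = prior_covariance),
            class = "kalman_state")
}

#' One Kalman filter predict-update step
#'
#' Standard linear-Gaussian predict (through the plant dynamics, including
#' any applied control) followed by a measurement update in Joseph form,
#' which preserves symmetry and positive semidefiniteness of the covariance.
#' If the innovation covariance is singular but the predicted covariance is
#' (numerically) zero there is nothing to learn and the update is skipped;
#' a singular innovation covariance with nonzero uncertainty is an error.
#'
#' @param state A [kalman_state()].
#' @param observation Observation vector (length = rows of \code{C}).
#' @param plant A \code{plant_model}, or any list with conformable
#'   \code{A}, \code{B}, \code{C}, \code{Q_proc}, \code{R_obs}.
#' @param control Control applied during the transition (default 0).
#' @return Updated [kalman_state()] with \code{prior_covariance} set.
#' @export
kalman_step <- function(state, observation, plant, control = 0) {
  A <- plant$A; B <- plant$B; C <- plant$C
  observation <- as.numeric(observation)
  if (length(observation) != nrow(C))
    stop("observation has length ", length(observation), ", expected ", nrow(C))
  m_pred <- as.numeric(A %*% state$mean + B %*% control)
  P_pred <- A %*% state$covariance %*% t(A) + plant$Q_proc
  P_pred <- (P_pred + t(P_pred)) / 2
  S <- C %*% P_pred %*% t(C) + plant$R_obs
  if (rcond(S) < .Machine$double.eps * 10) {
    if (max(abs(P_pred)) < 1e-12)
      return(kalman_state(m_pred, P_pred, prior_covariance = P_pred))
    stop("innovation covariance is singular; observation model is degenerate")
  }
  K <- P_pred %*% t(C) %*% solve(S)
  innov <- observation - as.numeric(C %*% m_pred)
  m_post <- m_pred + as.numeric(K %*% innov)
  IKC <- diag(nrow(A)) - K %*% C
  P_post <- IKC %*% P_pred %*% t(IKC) + K %*% plant$R_obs %*% t(K)
  kalman_state(m_post, P_post, prior_covariance = P_pred)
}

#' Steady-state Kalman filter quantities
#'
#' Iterates the covariance (Riccati) recursion to its fixed point and
#' returns the stationary prior and posterior covariances and gain.
#'
#' @param plant A \code{plant_model} or conformable list.
#' @param tol Convergence tolerance on the prior covariance.
#' @param max_iter Iteration cap.
#' @return List with \code{prior}, \code{posterior}, \code{gain},
#'   \code{iterations}.
#' @export
steady_state_kalman <- function(plant, tol = 1e-11, max_iter = 10000) {
  A <- plant$A; C <- plant$C
  P <- plant$Q_proc
  for (i in seq_len(max_iter)) {
    S <- C %*% P %*% t(C) + plant$R_obs
    K <- P %*% t(C) %*% solve(S)
    IKC <- diag(nrow(A)) - K %*% C
    Ppost <- IKC %*% P %*% t(IKC) + K %*% plant$R_obs %*% t(K)
    Pnew <- A %*% Ppost %*% t(A) + plant$Q_proc
    Pnew <- (Pnew + t(Pnew)) / 2
    if (max(abs(Pnew - P)) < tol) {
      return(list(prior = Pnew, posterior = Ppost, gain = K, iterations = i))
    }
    P <- Pnew
  }
  warning("Kalman covariance recursion did not converge to ", tol,
          " in ", max_iter, " iterations")
  list(prior = P, posterior = Ppost, gain = K, iterations = max_iter)
}

#' Simulate closed-loop tracking
#'
#' Rolls out the tracking task: the true joystick propagates through its
#' spring-mass dynamics driven by the (motor-delayed) control and motor
#' noise; the target states follow the supplied pre-generated trajectory;
#' observations (joystick position, visually delayed target position) are
#' corrupted by observation noise; a steady-state Kalman filter updates the
#' state estimate; the receding-horizon controller outputs the next control.
#' Deterministic given \code{seed}.
#'
#' @param plant A [build_plant()] model whose target dynamics match the
#'   generator of \code{target}.
#' @param target A [generate_target()] signal (or numeric vector).
#' @param seed RNG seed for motor, representation and observation noise.
#' @param transient Initial frames dropped from the returned pair
#'   (default 200).
#' @param divergence_bound Cursor magnitude that triggers an instability
#'   error.
#' @return Object of class \code{"sim_run"}: \code{pair}
#'   ([trajectory_pair()]), \code{controls}, \code{kalman_trace} (stationary
#'   covariances, gain, and the sample covariance of the noise-driven true
#'   states), \code{ground_truth} (named \code{tfb}, \code{tff} in
#'   bits/sample), \code{true_vmd}.
#' @export
simulate_tracking <- function(plant, target, seed = 1, transient = 200,
                              divergence_bound = 1e6) {
  stopifnot(inherits(plant, "plant_model"))
  frame_rate <- 60
  if (inherits(target, "target_signal")) {
    frame_rate <- target$config$frame_rate
    x <- target$positions
  } else x <- as.numeric(target)
  T <- length(x)
  if (T <= transient + 100) stop("target too short for transient of ", transient)
  ss <- steady_state_kalman(plant)
  idx <- plant$idx
  n <- nrow(plant$A)
  m <- plant$motor_delay; v <- plant$visual_delay
  sm <- plant$spring_mass
  obs_sd <- sqrt(diag(plant$R_obs))
  noise <- withr_seed(seed, list(
    motor = stats::rnorm(T, sd = plant$sigmas["motor"]),
    err = stats::rnorm(T, sd = plant$sigmas["err"]),
    obs = matrix(stats::rnorm(2 * T), T, 2) %*% diag(obs_sd)
  ))
  s_true <- numeric(n)
  mhat <- numeric(n)
  u_prev <- 0
  y <- numeric(T); controls <- numeric(T)
  state_rows <- matrix(0, T, 3)  # noise-driven coords, for the marginal covariance
  K <- ss$gain; A <- plant$A; B <- plant$B; C <- plant$C
  for (t in seq_len(T)) {
    # -- true state propagation (target states implanted from the series)
    j_prev1 <- s_true[idx$j1]; j_prev2 <- s_true[idx$j2]
    u_in <- if (m > 0) s_true[idx$motor[m]] else u_prev
    j_new <- sm[1] * j_prev1 + sm[2] * j_prev2 + u_in + noise$motor[t]
    if (m > 0) {
      line <- s_true[idx$motor]
      s_true[idx$motor] <- c(u_prev, line[-m])
    }
    s_true[idx$j1] <- j_prev2
    s_true[idx$j2] <- j_new
    s_true[idx$x1] <- if (t >= 2) x[t - 1] else 0
    s_true[idx$x2] <- x[t]
    if (v > 0) s_true[idx$visual] <- ifelse(t - seq_len(v) >= 1, x[pmax(t - seq_len(v), 1)], 0)
    s_true[idx$e] <- x[t] - j_new + noise$err[t]
    if (!is.finite(j_new) || abs(j_new) > divergence_bound)
      stop("simulation diverged at frame ", t, " (|cursor| > ", divergence_bound, ")")
    # -- observation and steady-state Kalman update
    obs <- as.numeric(C %*% s_true) + noise$obs[t, ]
    m_pred <- as.numeric(A %*% mhat + B %*% u_prev)
    mhat <- m_pred + as.numeric(K %*% (obs - as.numeric(C %*% m_pred)))
    # -- receding-horizon control
    u_prev <- mpc_control(mhat, plant)
    controls[t] <- u_prev
    y[t] <- j_new
    state_rows[t, ] <- s_true[idx$noise_driven]
  }
  keep <- (transient + 1):T
  pair <- trajectory_pair(x[keep], y[keep], frame_rate)
  trace <- list(prior_covariance = ss$prior, posterior_covariance = ss$posterior,
                gain = ss$gain, iterations = ss$iterations,
                state_cov = stats::cov(state_rows[keep, , drop = FALSE]),
                n_steps = T, transient = transient)
  run <- structure(
    list(pair = pair, controls = controls[keep], kalman_trace = trace,
         true_vmd = plant$effective_vmd, seed = seed),
    class = "sim_run"
  )
  run$ground_truth <- c(tfb = ground_truth_tfb(trace, plant),
                        tff = ground_truth_tff(trace, plant))
  run
}

#' @rdname simulate_tracking
#' @param object A \code{plant_model} (S3 \code{simulate} method).
#' @param nsim Number of runs.
#' @param ... Passed to [simulate_tracking()] (must include \code{target}).
#' @export
simulate.plant_model <- function(object, nsim = 1, seed = 1, ...) {
  runs <- lapply(seq_len(nsim), function(i)
    simulate_tracking(object, seed = seed + i - 1, ...))
  if (nsim == 1) runs[[1]] else runs
}

#' @export
print.sim_run <- function(x, ...) {
  cat("LQG tracking simulation run\n")
  cat(sprintf("  %d frames kept, true VMD %d frames, seed %d\n",
              length(x$pair$target), x$true_vmd, x$seed))
  cat(sprintf("  ground truth: TFB = %.4f, TFF = %.4f bits/sample\n",
              x$ground_truth["tfb"], x$ground_truth["tff"]))
  invisible(x)
}

#' Ground-truth feedback information of the model
#'
#' Information carried by one observation about the state at the Kalman
#' filter level, conditioned on the observation history:
#' \deqn{T_{FB} = \frac{1}{2}\log_2\frac{|C\Sigma C^T + R|}{|R|}}
#' with \eqn{\Sigma} the steady-state prior (pre-update) state covariance
#' and R the observation-noise covariance. Nonnegative; zero when the
#' observations are uninformative (huge R) or there is nothing left to learn
#' (\eqn{\Sigma \to 0}).
#'
#' @param kalman_trace The \code{kalman_trace} of a [simulate_tracking()]
#'   run, a [kalman_state()] with \code{prior_covariance}, or a covariance
#'   matrix.
#' @param plant The \code{plant_model}.
#' @return Bits per sample (scalar).
#' @export
ground_truth_tfb <- function(kalman_trace, plant) {
  P <- .extract_prior(kalman_trace)
  detR <- det(plant$R_obs)
  if (detR <= 0) stop("observation-noise covariance is singular; TFB undefined")
  S <- plant$C %*% P %*% t(plant$C) + plant$R_obs
  0.5 * (determinant(S)$modulus[1] - log(detR)) / log(2)
}

#' Ground-truth feedforward information of the model
#'
#' Information shared by successive states, \eqn{T_{FF} = I(s_{t-1}; s_t) =
#' \frac{1}{2}\log_2(|\Sigma|/|Q|)}, with \eqn{\Sigma} the stationary
#' marginal covariance of the state process and Q the process-noise
#' covariance (the conditional covariance of \eqn{s_t} given
#' \eqn{s_{t-1}}). Both determinants are evaluated on the noise-driven
#' coordinates (joystick dynamic state, target dynamic state, error state):
#' delay-line coordinates carry no process noise, so the full-state Q is
#' singular and the ratio is only defined on this subspace.
#'
#' @param kalman_trace The \code{kalman_trace} of a run (its
#'   \code{state_cov} is the sample covariance of the noise-driven true
#'   states), or a 3 x 3 covariance matrix for that subspace.
#' @param plant The \code{plant_model}.
#' @return Bits per sample (scalar, >= 0 up to sampling error).
#' @export
ground_truth_tff <- function(kalman_trace, plant) {
  Sigma <- if (is.matrix(kalman_trace)) kalman_trace else kalman_trace$state_cov
  idx <- plant$idx$noise_driven
  Qs <- plant$Q_proc[idx, idx]
  dq <- det(Qs)
  if (dq <= 0)
    stop("process noise is singular on the noise-driven subspace; TFF undefined")
  if (!all(dim(Sigma) == length(idx)))
    stop("state covariance must be ", length(idx), " x ", length(idx))
  0.5 * (determinant(Sigma)$modulus[1] - log(dq)) / log(2)
}

.extract_prior <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "kalman_state")) {
    if (is.null(x$prior_covariance))
      stop("kalman_state carries no prior covariance")
    return(x$prior_covariance)
  }
  x$prior_covariance
}
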