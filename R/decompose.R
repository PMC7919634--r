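#' Paired target/tracking trajectories
#'
#' Container for one trial of a visuomotor tracking task: the target position
#' series X and the cursor (tracking) series Y, sampled at a common fixed
#' frame rate.
#'
#' @param target Numeric vector of target positions (one per frame).
#' @param tracking Numeric vector of cursor positions, same length.
#' @param frame_rate Frames per second (default 60).
#' @return Object of class \code{"trajectory_pair"}.
#' @export
trajectory_pair <- function(target, tracking, frame_rate = 60) {
  if (inherits(target, "target_signal")) {
    frame_rate <- target$config$frame_rate
    target <- target$positions
  }
  target <- as.numeric(target); tracking <- as.numeric(tracking)
  if (length(target) != length(tracking))
    stop("target and tracking must have equal length (",
         length(target), " vs ", length(tracking), ")")
  if (anyNA(target) || anyNA(tracking) ||
      any(!is.finite(target)) || any(!is.finite(tracking)))
    stop("trajectories contain non-finite values")
  if (frame_rate <= 0) stop("`frame_rate` must be > 0")
  structure(list(target = target, tracking = tracking, frame_rate = frame_rate),
            class = "trajectory_pair")
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat(sprintf("Trajectory pair: %d frames at %g Hz (target sd %.3f, tracking sd %.3f)\n",
              length(x$target), x$frame_rate, stats::sd(x$target), stats::sd(x$tracking)))
  invisible(x)
}

#' @export
plot.trajectory_pair <- function(x, n = 600, ...) {
  idx <- seq_len(min(n, length(x$target)))
  t <- idx / x$frame_rate
  graphics::matplot(t, cbind(x$target[idx], x$tracking[idx]), type = "l",
                    lty = 1, col = c("steelblue", "darkorange"),
                    xlab = "time (s)", ylab = "position", ...)
  graphics::legend("topright", c("target", "tracking"), lty = 1,
                   col = c("steelblue", "darkorange"), bty = "n")
  invisible(x)
}

# Lagged design shared by the feedback measure and the TE latency scan.
# Rows are frames t = (d+2) .. n so all lags t-d-1 >= 1 exist.
.lagged_design <- function(pair, d) {
  n <- length(pair$target)
  t <- (d + 2):n
  list(
    y  = pair$tracking[t],
    xp = cbind(pair$target[t - d], pair$target[t - d - 1]),          # X_{t-d}, X_{t-d-1}
    z  = cbind(pair$tracking[t - d], pair$tracking[t - d - 1],       # Y_{t-d}, Y_{t-d-1}
               pair$tracking[t - 1]),                                # Y_{t-1}
    x4 = cbind(pair$target[t], pair$target[t - 1],                   # X_t, X_{t-1}
               pair$target[t - d], pair$target[t - d - 1])
  )
}

.check_pair_delay <- function(pair, vmd, min_delay = 2) {
  stopifnot(inherits(pair, "trajectory_pair"))
  if (vmd < min_delay) stop("`vmd` must be >= ", min_delay, " frames")
  if (vmd >= length(pair$target) / 10)
    stop("`vmd` (", vmd, ") too large for series of length ", length(pair$target))
  if (stats::sd(pair$tracking) == 0)
    stop("degenerate (constant) tracking series")
  if (stats::sd(pair$target) == 0)
    stop("degenerate (constant) target series")
}

#' Feedback information per sample
#'
#' Real-time (error-correcting) information transferred from target X to
#' tracking Y at the visuomotor delay: the conditional mutual information
#' \deqn{I_{FB} = I(Y_t;\; \{X_{t-VMD}, X_{t-VMD-1}\} \mid
#'   \{Y_{t-VMD}, Y_{t-VMD-1}, Y_{t-1}\})}
#' estimated with the Gaussian copula. History depths are 2 on both sides
#' because the target carries autocorrelation of order 2; the additional
#' conditioning on \eqn{Y_{t-1}} makes successive samples of the measure
#' independent, so it is a per-sample rate (multiply by the frame rate for
#' bits/s, see [rate_per_second()]).
#'
#' @param pair A [trajectory_pair()].
#' @param vmd Visuomotor delay in frames (>= 2).
#' @param bias_correct Apply the log-determinant bias correction.
#' @return Feedback information in bits/sample (scalar).
#' @export
compute_ifb <- function(pair, vmd, bias_correct = TRUE) {
  .check_pair_delay(pair, vmd)
  d <- .lagged_design(pair, vmd)
  cmi_copula(d$y, d$xp, d$z, bias_correct = bias_correct)$value
}

#' Total shared information per sample
#'
#' Joint mutual information between the tracking sample and the four target
#' copies that can influence it, either by prediction (\eqn{X_t, X_{t-1}}) or
#' by delayed feedback (\eqn{X_{t-VMD}, X_{t-VMD-1}}):
#' \deqn{I_{total} = I(Y_t;\; \{X_t, X_{t-1}, X_{t-VMD}, X_{t-VMD-1}\}).}
#'
#' @inheritParams compute_ifb
#' @return Total information in bits/sample (scalar).
#' @export
compute_itotal <- function(pair, vmd, bias_correct = TRUE) {
  .check_pair_delay(pair, vmd)
  d <- .lagged_design(pair, vmd)
  mi_copula(d$x4, d$y, bias_correct = bias_correct)$value
}

#' Feedforward (predictive) information per sample
#'
#' The share of the total target/tracking information not attributable to
#' delayed real-time transfer: \eqn{I_{FF} = I_{total} - I_{FB}} (exact
#' arithmetic difference).
#'
#' @inheritParams compute_ifb
#' @return Feedforward information in bits/sample (scalar).
#' @export
compute_iff <- function(pair, vmd, bias_correct = TRUE) {
  compute_itotal(pair, vmd, bias_correct) - compute_ifb(pair, vmd, bias_correct)
}

#' Convert a per-sample information rate to bits per second
#'
#' @param ifb Information in bits/sample.
#' @param frame_rate Samples per second.
#' @return Bits per second.
#' @export
rate_per_second <- function(ifb, frame_rate) {
  if (frame_rate <= 0) stop("`frame_rate` must be > 0")
  ifb * frame_rate
}

#' Decompose tracking information into feedback and feedforward components
#'
#' The main fitting function: computes \eqn{I_{FB}}, \eqn{I_{total}} and
#' \eqn{I_{FF} = I_{total} - I_{FB}} for one trial at a given (or estimated)
#' visuomotor delay.
#'
#' @param pair A [trajectory_pair()].
#' @param vmd Visuomotor delay in frames; if \code{NULL} it is estimated as
#'   the transfer-entropy peak latency over \code{d_range}.
#' @param d_range Candidate delay range used when \code{vmd} is estimated.
#' @param bias_correct Apply the log-determinant bias correction.
#' @return Object of class \code{"info_decomp"}: list with \code{ifb},
#'   \code{itotal}, \code{iff} (bits/sample), \code{vmd} (frames),
#'   \code{ifb_per_second} (bits/s), \code{frame_rate}, \code{n}.
#' @examples
#' ts <- generate_target(signal_config(a1 = 2, n_frames = 4500, seed = 7))
#' x <- ts$positions
#' y <- c(rep(0, 12), x[1:(length(x) - 12)]) + rnorm(length(x), sd = 0.2)
#' decompose_tracking(trajectory_pair(x, y), vmd = 12)
#' @export
decompose_tracking <- function(pair, vmd = NULL, d_range = c(2, 30),
                               bias_correct = TRUE) {
  if (is.null(vmd)) {
    curve <- te_latency_curve(pair, d_range[1], d_range[2], n_surrogates = 0)
    vmd <- curve$peak_delay
  }
  ifb <- compute_ifb(pair, vmd, bias_correct)
  itotal <- compute_itotal(pair, vmd, bias_correct)
  structure(
    list(ifb = ifb, itotal = itotal, iff = itotal - ifb, vmd = vmd,
         ifb_per_second = rate_per_second(ifb, pair$frame_rate),
         frame_rate = pair$frame_rate, n = length(pair$target)),
    class = "info_decomp"
  )
}

#' @export
print.info_decomp <- function(x, ...) {
  cat("Tracking information decomposition (VMD =", x$vmd, "frames)\n")
  cat(sprintf("  feedback    IFB    = %8.4f bits/sample  (%.2f bits/s at %g Hz)\n",
              x$ifb, x$ifb_per_second, x$frame_rate))
  cat(sprintf("  feedforward IFF    = %8.4f bits/sample\n", x$iff))
  cat(sprintf("  total       Itotal = %8.4f bits/sample   [n = %d frames]\n",
              x$itotal, x$n))
  invisible(x)
}

#' @export
summary.info_decomp <- function(object, ...) {
  out <- c(ifb = object$ifb, iff = object$iff, itotal = object$itotal,
           vmd = object$vmd, ifb_per_second = object$ifb_per_second)
  class(out) <- "summary.info_decomp"
  out
}

#' @export
print.summary.info_decomp <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' @export
coef.info_decomp <- function(object, ...) {
  c(ifb = object$ifb, iff = object$iff, itotal = object$itotal)
}

#' Transfer-entropy latency curve
#'
#' Evaluates the feedback conditional-MI form at every candidate delay d and
#' locates the peak. Because feedback transfer is delayed by the visuomotor
#' delay, the curve peaks at the system's effective delay, which is how the
#' VMD is estimated from data. Ties break toward the smallest delay.
#'
#' Uncertainty of the peak value is obtained by circular-shift surrogates of
#' the target series (seeded; shifts exceed \code{d_max} so all lagged
#' structure is destroyed while the marginals are preserved). The peak is
#' flagged low-confidence when it does not exceed the curve median by three
#' surrogate standard deviations.
#'
#' @param pair A [trajectory_pair()].
#' @param d_min,d_max Candidate delay range in frames (\code{2 <= d_min <
#'   d_max < length/10}).
#' @param n_surrogates Number of circular-shift surrogates for the
#'   significance flag (0 skips the flag).
#' @param bias_correct Apply the log-determinant bias correction.
#' @param seed Seed for the surrogate shifts.
#' @return Object of class \code{"te_curve"}: \code{delays},
#'   \code{te_values} (bits/sample), \code{peak_delay}, \code{peak_value},
#'   \code{surrogate_sd}, \code{low_confidence}.
#' @export
te_latency_curve <- function(pair, d_min = 2, d_max = 30, n_surrogates = 100,
                             bias_correct = TRUE, seed = 1) {
  if (d_min < 2 || d_min >= d_max) stop("need 2 <= d_min < d_max")
  .check_pair_delay(pair, d_max, min_delay = d_min)
  delays <- d_min:d_max
  te <- vapply(delays, function(d) compute_ifb(pair, d, bias_correct), numeric(1))
  peak_i <- which.max(te)  # first maximum = smallest delay on ties
  peak_delay <- delays[peak_i]
  surrogate_sd <- NA_real_
  low_confidence <- NA
  if (n_surrogates > 0) {
    n <- length(pair$target)
    shifts <- withr_seed(seed, sample((d_max + 1):(n - d_max - 1), n_surrogates,
                                      replace = TRUE))
    surr <- vapply(shifts, function(s) {
      xs <- pair$target[c((s + 1):n, 1:s)]
      sp <- trajectory_pair(xs, pair$tracking, pair$frame_rate)
      compute_ifb(sp, peak_delay, bias_correct)
    }, numeric(1))
    surrogate_sd <- stats::sd(surr)
    low_confidence <- (te[peak_i] - stats::median(te)) < 3 * surrogate_sd
  }
  structure(
    list(delays = delays, te_values = te, peak_delay = peak_delay,
         peak_value = te[peak_i], surrogate_sd = surrogate_sd,
         low_confidence = low_confidence),
    class = "te_curve"
  )
}

#' @export
print.te_curve <- function(x, ...) {
  cat(sprintf("Transfer-entropy latency curve over d = %d..%d frames\n",
              min(x$delays), max(x$delays)))
  cat(sprintf("  peak at d = %d (%.4f bits/sample)%s\n", x$peak_delay, x$peak_value,
              if (isTRUE(x$low_confidence)) "  [LOW CONFIDENCE]" else ""))
  invisible(x)
}

#' @export
plot.te_curve <- function(x, ...) {
  graphics::plot(x$delays, x$te_values, type = "b", pch = 16,
                 xlab = "candidate delay d (frames)", ylab = "TE (bits/sample)", ...)
  graphics::abline(v = x$peak_delay, lty = 2, col = "grey50")
  invisible(x)
}

#' Estimate the visuomotor delay from one or more trials
#'
#' Per-trial transfer-entropy peak latencies, averaged across trials; the
#' dispersion is the across-trial standard deviation (\code{NA} for a single
#' trial). Trials whose peak is flagged low-confidence are dropped with a
#' warning; if all trials are low-confidence the estimate fails.
#'
#' @param trials A \code{trajectory_pair} or list of them.
#' @param d_min,d_max Candidate delay range (frames).
#' @param n_surrogates Surrogates per trial for the confidence flag.
#' @param ... Passed to [te_latency_curve()].
#' @return Object of class \code{"vmd_estimate"}: \code{vmd} (mean frames),
#'   \code{sd}, \code{per_trial}, \code{n_trials}.
#' @export
estimate_vmd <- function(trials, d_min = 2, d_max = 30, n_surrogates = 100, ...) {
  if (inherits(trials, "trajectory_pair")) trials <- list(trials)
  if (length(trials) < 1L) stop("need at least one trial")
  curves <- lapply(trials, te_latency_curve, d_min = d_min, d_max = d_max,
                   n_surrogates = n_surrogates, ...)
  peaks <- vapply(curves, `[[`, numeric(1), "peak_delay")
  low <- vapply(curves, function(cv) isTRUE(cv$low_confidence), logical(1))
  if (all(low)) stop("all trials have low-confidence transfer-entropy peaks; ",
                     "no reliable VMD estimate")
  if (any(low)) {
    warning(sum(low), " low-confidence trial(s) dropped from the VMD estimate")
    peaks <- peaks[!low]
  }
  structure(
    list(vmd = mean(peaks), sd = if (length(peaks) > 1) stats::sd(peaks) else NA_real_,
         per_trial = peaks, n_trials = length(peaks)),
    class = "vmd_estimate"
  )
}

#' @export
print.vmd_estimate <- function(x, ...) {
  cat(sprintf("Estimated VMD: %.2f frames (sd %s, %d trial%s)\n", x$vmd,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd), x$n_trials,
              if (x$n_trials == 1) "" else "s"))
  invisible(x)
}

#' Performance lag
#'
#' The integer lag (frames) maximizing the cross-correlation between the
#' mean-removed target and tracking series, i.e. by how much the response
#' trails the target. When prediction compensates for the visuomotor delay
#' the performance lag falls below the VMD. Ties break toward the smallest
#' lag; lags 0..\code{max_lag} are scanned.
#'
#' @param pair A [trajectory_pair()].
#' @param max_lag Largest lag scanned (frames, < length/4).
#' @return Integer lag in frames.
#' @export
performance_lag <- function(pair, max_lag = 40) {
  stopifnot(inherits(pair, "trajectory_pair"))
  n <- length(pair$target)
  if (max_lag >= n / 4) stop("`max_lag` must be < length/4")
  if (stats::sd(pair$target) == 0 || stats::sd(pair$tracking) == 0)
    stop("constant series: cross-correlation undefined")
  x <- pair$target - mean(pair$target)
  y <- pair$tracking - mean(pair$tracking)
  cc <- vapply(0:max_lag, function(l) {
    t <- (l + 1):n
    stats::cor(x[t - l], y[t])
  }, numeric(1))
  (0:max_lag)[which.max(cc)]
}
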