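#' Target-signal configuration
#'
#' Parameters of the pre-programmed one-dimensional target trajectory: white
#' noise passed through a second-order (sinusoidal) filter. Two filter
#' parameterizations are provided:
#' \describe{
#'   \item{\code{form = "resonator"} (default)}{a stable AR(2) resonator with
#'     pole angle \code{pi/100} rad/frame (period about 200 frames, 3.3 s at
#'     60 Hz) and pole radius \code{r = exp(-a1/50)}:
#'     \code{x_t = 2 r cos(pi/100) x_{t-1} - r^2 x_{t-2} + e_t/a1}. Larger
#'     \code{a1} pushes the poles off the unit circle, widening the band and
#'     letting more driving noise through: the signal becomes less
#'     predictable (more complex).}
#'   \item{\code{form = "printed"}}{the literal recurrence
#'     \code{a1 x_t = e_t + a2 x_{t-1} + x_{t-2}}, \code{a2 = -2 a1
#'     cos(pi/100)}. Its characteristic roots lie outside the unit circle for
#'     every \code{a1 > 0}, so generation fails with an instability error;
#'     it is kept for reference and for the instability contract.}
#' }
#'
#' @param a1 Filter complexity parameter (> 0). Larger = less predictable.
#' @param n_frames Total frames generated before burn-in removal.
#' @param frame_rate Samples per second (default 60).
#' @param burn_in Initial frames discarded to remove the transient
#'   (default 500; initial conditions are zero).
#' @param seed RNG seed (integer) making generation deterministic.
#' @param noise_sd Standard deviation of the driving white noise.
#' @param normalize If \code{TRUE} (default), rescale so the stationary
#'   standard deviation is 1 ("screen units"), using the closed-form AR(2)
#'   stationary variance; the implied innovation sd is then
#'   \code{sd_innovation(config)}. Amplitude is thereby held constant across
#'   predictability levels, as on a fixed-width display.
#' @param form \code{"resonator"} or \code{"printed"} (see Details).
#' @return Object of class \code{"signal_config"}.
#' @export
signal_config <- function(a1 = 1, n_frames = 10500, frame_rate = 60,
                          burn_in = 500, seed = 1, noise_sd = 1,
                          normalize = TRUE,
                          form = c("resonator", "printed")) {
  form <- match.arg(form)
  if (!is.numeric(a1) || length(a1) != 1L || a1 <= 0) stop("`a1` must be a single value > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (frame_rate <= 0) stop("`frame_rate` must be > 0")
  if (burn_in < 0 || n_frames <= burn_in)
    stop("need n_frames > burn_in >= 0 (got ", n_frames, ", ", burn_in, ")")
  structure(
    list(a1 = a1, n_frames = as.integer(n_frames), frame_rate = frame_rate,
         burn_in = as.integer(burn_in), seed = as.integer(seed),
         noise_sd = noise_sd, normalize = isTRUE(normalize), form = form,
         theta = pi / 100),
    class = "signal_config"
  )
}

#' @export
print.signal_config <- function(x, ...) {
  cat("Target signal config (", x$form, " form)\n", sep = "")
  cat(sprintf("  a1 = %g, frames = %d (burn-in %d), %g Hz, noise sd = %g, seed = %d\n",
              x$a1, x$n_frames, x$burn_in, x$frame_rate, x$noise_sd, x$seed))
  ar <- ar_coefficients(x)
  cat(sprintf("  AR(2): phi1 = %.5f, phi2 = %.5f%s\n", ar[1], ar[2],
              if (x$normalize) ", normalized to unit stationary sd" else ""))
  invisible(x)
}

#' AR(2) coefficients implied by a signal configuration
#'
#' For the resonator form, \code{phi1 = 2 r cos(theta)}, \code{phi2 = -r^2}
#' with \code{r = exp(-a1/50)}; for the printed form the recurrence
#' rearranges to \code{phi1 = -2 cos(theta)}, \code{phi2 = 1/a1}.
#'
#' @param config A \code{signal_config}.
#' @return Numeric vector \code{c(phi1, phi2)}.
#' @export
ar_coefficients <- function(config) {
  stopifnot(inherits(config, "signal_config"))
  if (config$form == "resonator") {
    r <- exp(-config$a1 / 50)
    c(2 * r * cos(config$theta), -r^2)
  } else {
    c(-2 * cos(config$theta), 1 / config$a1)
  }
}

# Stationary variance of a stable AR(2) with unit innovation variance
# (Yule-Walker): var = (1 - phi2) / ((1 + phi2) ((1 - phi2)^2 - phi1^2)).
.ar2_var_unit <- function(phi) {
  p1 <- phi[1]; p2 <- phi[2]
  denom <- (1 + p2) * ((1 - p2)^2 - p1^2)
  if (denom <= 0) return(NA_real_)
  (1 - p2) / denom
}

#' Innovation standard deviation of the generated signal
#'
#' The driving-noise sd after the filter's \code{1/a1} pass-through and, when
#' \code{normalize = TRUE}, after rescaling to unit stationary sd. This is
#' the process-noise magnitude a state-space model of the target must use.
#'
#' @param config A \code{signal_config} (resonator form).
#' @return Innovation sd (scalar).
#' @export
sd_innovation <- function(config) {
  stopifnot(inherits(config, "signal_config"))
  raw <- config$noise_sd / config$a1
  if (!config$normalize || raw == 0) return(raw)
  v <- .ar2_var_unit(ar_coefficients(config))
  if (!is.finite(v)) stop("unstable configuration; stationary variance undefined")
  1 / sqrt(v)  # raw * (1 / (raw * sqrt(v)))
}

#' Generate a target trajectory
#'
#' Runs the configured second-order recurrence driven by seeded white noise,
#' from zero initial conditions, and discards the burn-in. The resonator form
#' yields a narrowband, sinusoidal-looking signal whose autocorrelation
#' structure is exactly order 2.
#'
#' @param config A [signal_config()].
#' @param instability_bound Magnitude at which the recurrence is declared
#'   divergent (default \code{1e6} times the driving noise sd).
#' @return Object of class \code{"target_signal"}: list with \code{positions}
#'   (length \code{n_frames - burn_in}) and \code{config}.
#' @examples
#' ts <- generate_target(signal_config(a1 = 1, n_frames = 2000, seed = 42))
#' plot(ts)
#' @export
generate_target <- function(config, instability_bound = NULL) {
  stopifnot(inherits(config, "signal_config"))
  phi <- ar_coefficients(config)
  sd_in <- config$noise_sd / config$a1
  if (is.null(instability_bound)) instability_bound <- 1e6 * max(config$noise_sd, 1)
  n <- config$n_frames
  x <- numeric(n)
  eps <- withr_seed(config$seed, stats::rnorm(n, sd = sd_in))
  # x_1 = x_2 = 0 initial conditions; recurrence from frame 3
  for (t in 3:n) {
    x[t] <- phi[1] * x[t - 1] + phi[2] * x[t - 2] + eps[t]
    if (!is.finite(x[t]) || abs(x[t]) > instability_bound)
      stop("unstable recurrence at frame ", t, " (|x| > ", instability_bound,
           ") for a1 = ", config$a1, " [form = ", config$form, "]")
  }
  x <- x[(config$burn_in + 1):n]
  if (config$normalize && config$noise_sd > 0) {
    v <- .ar2_var_unit(phi)
    if (!is.finite(v)) stop("unstable configuration; cannot normalize")
    x <- x / (sd_in * sqrt(v))
  }
  structure(list(positions = x, config = config), class = "target_signal")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' @export
print.target_signal <- function(x, ...) {
  cat(sprintf("Target signal: %d frames at %g Hz (a1 = %g, %s form), sd = %.3f\n",
              length(x$positions), x$config$frame_rate, x$config$a1,
              x$config$form, stats::sd(x$positions)))
  invisible(x)
}

#' @export
plot.target_signal <- function(x, n = 600, ...) {
  idx <- seq_len(min(n, length(x$positions)))
  graphics::plot(idx / x$config$frame_rate, x$positions[idx], type = "l",
                 xlab = "time (s)", ylab = "target position", ...)
  invisible(x)
}

#' Partial autocorrelation of a target signal
#'
#' Partial autocorrelations at lags 1..\code{max_lag}, used to verify that
#' the generated targets carry autocorrelation of order exactly 2: for an
#' AR(2) process the PACF beyond lag 2 is indistinguishable from zero
#' (within about \code{2/sqrt(N)} on long realizations).
#'
#' @param signal A \code{target_signal} or numeric vector.
#' @param max_lag Largest lag (frames); must be < series length.
#' @return Numeric vector of partial autocorrelations, names = lags.
#' @export
autocorrelation_order_check <- function(signal, max_lag = 10) {
  x <- if (inherits(signal, "target_signal")) signal$positions else as.numeric(signal)
  if (max_lag >= length(x)) stop("max_lag must be smaller than the series length")
  if (stats::sd(x) == 0) stop("constant series: partial autocorrelation undefined")
  p <- stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  names(p) <- seq_len(max_lag)
  p
}
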