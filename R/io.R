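#' Write a trajectory (pair) to CSV
#'
#' Columns are \code{frame} (0-based), \code{target_x} and, for a pair,
#' \code{cursor_x}.
#'
#' @param x A [trajectory_pair()] or [generate_target()] signal.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  if (inherits(x, "target_signal")) {
    df <- data.frame(frame = seq_along(x$positions) - 1L, target_x = x$positions)
  } else if (inherits(x, "trajectory_pair")) {
    df <- data.frame(frame = seq_along(x$target) - 1L,
                     target_x = x$target, cursor_x = x$tracking)
  } else stop("`x` must be a target_signal or trajectory_pair")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read paired trajectories from CSV
#'
#' Expects columns \code{frame}, \code{target_x}, \code{cursor_x} and an
#' optional \code{trial} column; rows are ordered by frame within trial. With
#' a \code{trial} column a list of [trajectory_pair()] objects is returned
#' (one per trial), otherwise a single pair.
#'
#' @param path CSV path.
#' @param frame_rate Sampling rate in Hz (default 60).
#' @return A \code{trajectory_pair} or list of them.
#' @export
read_trajectory_csv <- function(path, frame_rate = 60) {
  df <- utils::read.csv(path)
  need <- c("frame", "target_x", "cursor_x")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  make_pair <- function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    trajectory_pair(d$target_x, d$cursor_x, frame_rate)
  }
  if ("trial" %in% names(df)) {
    lapply(split(df, df$trial), make_pair)
  } else make_pair(df)
}

#' Read a signal configuration from JSON
#'
#' @param path JSON file with any of the [signal_config()] fields.
#' @return A \code{signal_config}.
#' @export
read_signal_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("a1", "n_frames", "frame_rate", "burn_in", "seed", "noise_sd",
             "normalize", "form")
  do.call(signal_config, cfg[intersect(names(cfg), known)])
}

#' Write a signal configuration to JSON
#'
#' @param config A \code{signal_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_signal_config <- function(config, path) {
  stopifnot(inherits(config, "signal_config"))
  jsonlite::write_json(unclass(config)[c("a1", "n_frames", "frame_rate",
                                         "burn_in", "seed", "noise_sd",
                                         "normalize", "form")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
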