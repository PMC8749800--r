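#' Construct a foot-motion signal
#'
#' Container for the multichannel inertial time series recorded by a single
#' foot-mounted sensor. Channels follow the sensor's sign conventions:
#' `A_y` acceleration is positive posteriorly and negative anteriorly, `A_z`
#' positive superiorly (so quiet stance sits near +1 g), and `G_x` angular
#' velocity is positive in plantarflexion and negative in dorsiflexion.
#' Accelerations are in g, angular velocities in deg/s, sole-to-ground angles
#' (optional) in deg, and time is in milliseconds on a uniform grid.
#'
#' @param t Time stamps in ms, strictly increasing with a constant step equal
#'   to `1000 / sample_rate`. If `NULL`, built from `sample_rate` and the
#'   channel length.
#' @param sample_rate Sampling frequency in Hz (positive scalar).
#' @param A_x,A_y,A_z Acceleration channels in g. `A_y` is required by the
#'   heel-strike and toe-off detectors.
#' @param G_x,G_y,G_z Angular-velocity channels in deg/s. `G_x` is the default
#'   detection channel for foot-flat and opposite-heel-strike.
#' @param E_x,E_y,E_z Optional sole-to-ground angles in deg.
#' @param side `"left"` or `"right"`: the instrumented foot.
#'
#' @return An object of class `foot_motion_signal`.
#' @export
foot_motion_signal <- function(t = NULL, sample_rate = 100,
                               A_x = NULL, A_y = NULL, A_z = NULL,
                               G_x = NULL, G_y = NULL, G_z = NULL,
                               E_x = NULL, E_y = NULL, E_z = NULL,
                               side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0)
  channels <- list(A_x = A_x, A_y = A_y, A_z = A_z,
                   G_x = G_x, G_y = G_y, G_z = G_z,
                   E_x = E_x, E_y = E_y, E_z = E_z)
  channels <- channels[!vapply(channels, is.null, logical(1))]
  if (!length(channels)) stop("at least one channel must be supplied")
  lens <- unique(vapply(channels, length, integer(1)))
  if (length(lens) != 1L)
    stop("all present channels must share the same length")
  n <- lens
  step <- 1000 / sample_rate
  if (is.null(t)) {
    t <- (seq_len(n) - 1) * step
  } else {
    if (length(t) != n)
      stop("t must have the same length as the channels")
    dt <- diff(t)
    if (n > 1L && (any(dt <= 0) || any(abs(dt - step) > 1e-6 * step))) {
      bad <- which(abs(dt - step) > 1e-6 * step | dt <= 0)[1L] + 1L
      stop(sprintf(
        "t must be strictly increasing with constant step %g ms; first bad row: %d",
        step, bad))
    }
  }
  structure(
    c(list(t = as.numeric(t), sample_rate = sample_rate, side = side), channels),
    class = "foot_motion_signal")
}

#' @export
print.foot_motion_signal <- function(x, ...) {
  chans <- intersect(c("A_x", "A_y", "A_z", "G_x", "G_y", "G_z",
                       "E_x", "E_y", "E_z"), names(x))
  cat(sprintf("<foot_motion_signal> %s foot, %d samples @ %g Hz (%.1f s)\n",
              x$side, length(x$t), x$sample_rate,
              (length(x$t) - 1) / x$sample_rate))
  cat("  channels:", paste(chans, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.foot_motion_signal <- function(x, ...) {
  chans <- intersect(c("A_x", "A_y", "A_z", "G_x", "G_y", "G_z",
                       "E_x", "E_y", "E_z"), names(x))
  out <- data.frame(t = x$t)
  for (ch in chans) out[[ch]] <- x[[ch]]
  out
}

# Sample period in ms.
sample_step <- function(signal) 1000 / signal$sample_rate

# Index of the sample at time t_ms (nearest sample).
time_to_index <- function(signal, t_ms) {
  i <- round((t_ms - signal$t[1]) / sample_step(signal)) + 1L
  as.integer(pmin(pmax(i, 1L), length(signal$t)))
}

# Pull one channel, with a clear error if absent.
get_channel <- function(signal, channel) {
  key <- switch(channel,
                Gx = "G_x", Ay = "A_y", Az = "A_z",
                channel)
  x <- signal[[key]]
  if (is.null(x)) stop(sprintf("channel %s is not present in the signal", key))
  x
}
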