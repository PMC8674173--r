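#' Remove gravity and low-pass filter raw acceleration
#'
#' Estimates gravity as the per-axis mean of the raw recording, subtracts
#' it, and applies a zero-phase (forward-backward) sixth-order Butterworth
#' low-pass to remove non-human high-frequency content. The subtracted mean
#' vector, renormalized, is stored as the `gravity_unit_vector` attribute;
#' any residual per-axis mean left by filter edge transients is removed so
#' the output is exactly zero-mean.
#'
#' @param recording Tibble with columns `time_s, ax, ay, az` and attribute
#'   `sampling_rate_hz` (or pass `sampling_rate_hz`).
#' @param cutoff_hz Low-pass cutoff (Hz), default 20; must be below Nyquist.
#' @param order Filter order (default 6).
#' @param sampling_rate_hz Overrides the recording attribute if given.
#' @return Tibble `time_s, ax, ay, az` of filtered, gravity-free
#'   acceleration with attributes `sampling_rate_hz` and
#'   `gravity_unit_vector`.
#' @export
remove_gravity_and_lowpass <- function(recording, cutoff_hz = 20, order = 6,
                                       sampling_rate_hz = NULL) {
  fs <- sampling_rate_hz %||% attr(recording, "sampling_rate_hz")
  if (is.null(fs)) abort("sampling_rate_hz not supplied")
  n <- nrow(recording)
  if (n == 0) abort("recording is empty")
  if (cutoff_hz >= fs / 2) abort("cutoff_hz must be below the Nyquist frequency")
  if (n <= 3 * (order + 1)) {
    abort("recording shorter than the filter warm-up length")
  }
  A <- as.matrix(recording[, c("ax", "ay", "az")])
  g <- unname(colMeans(A))
  gnorm <- sqrt(sum(g^2))
  gu <- if (gnorm > 0) g / gnorm else c(0, 0, 1)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  F <- apply(sweep(A, 2, g), 2, function(col) signal::filtfilt(bf, col))
  F <- sweep(F, 2, colMeans(F))  # edge transients leave a tiny residual mean
  out <- tibble(time_s = recording$time_s,
                ax = F[, 1], ay = F[, 2], az = F[, 3])
  attr(out, "sampling_rate_hz") <- fs
  attr(out, "gravity_unit_vector") <- gu
  out
}

#' Integrate acceleration to velocity and band-pass to remove drift
#'
#' Cumulative trapezoidal integration per axis followed by a zero-phase
#' sixth-order Butterworth band-pass (default 0.1-20 Hz) that removes
#' integration drift and residual high-frequency noise. The band-pass is
#' designed as `signal::butter(order/2, c(low, high), "pass")`, which gives
#' an order-`order` band-pass transfer function.
#'
#' @param acc Filtered acceleration tibble from
#'   [remove_gravity_and_lowpass()].
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz < Nyquist`.
#' @param order Overall band-pass order (even; default 6).
#' @param sampling_rate_hz Overrides the attribute if given.
#' @return Tibble `time_s, vx, vy, vz` (m/s, still sensor-frame) carrying
#'   forward the `sampling_rate_hz` and `gravity_unit_vector` attributes.
#' @export
integrate_and_bandpass <- function(acc, low_hz = 0.1, high_hz = 20,
                                   order = 6, sampling_rate_hz = NULL) {
  fs <- sampling_rate_hz %||% attr(acc, "sampling_rate_hz")
  if (is.null(fs)) abort("sampling_rate_hz not supplied")
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < fs / 2,
            order %% 2 == 0)
  n <- nrow(acc)
  if (n <= 3 * (order + 1)) {
    abort("series shorter than the filter warm-up length")
  }
  A <- as.matrix(acc[, c("ax", "ay", "az")])
  V <- apply(A, 2, function(col) pracma::cumtrapz(col)[, 1] / fs)
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  V <- apply(V, 2, function(col) signal::filtfilt(bf, col))
  out <- tibble(time_s = acc$time_s, vx = V[, 1], vy = V[, 2], vz = V[, 3])
  attr(out, "sampling_rate_hz") <- fs
  attr(out, "gravity_unit_vector") <- attr(acc, "gravity_unit_vector")
  out
}

#' Rotate a velocity series into anatomical body axes
#'
#' The rostrocaudal (RC) axis is aligned with the stored gravity direction;
#' the anteroposterior (AP) axis is the first principal direction of the
#' velocity projected onto the plane orthogonal to gravity; mediolateral
#' (ML) completes the right-handed orthonormal triad. The AP sign is fixed
#' so the single largest-distance velocity excursion (between consecutive
#' zero-crossings) is positive, i.e. points towards the reaching target.
#'
#' @param vel Velocity tibble from [integrate_and_bandpass()].
#' @param gravity_unit_vector Unit 3-vector; defaults to the attribute
#'   carried on `vel`.
#' @return Tibble `time_s, v_ap, v_ml, v_rc` with attributes
#'   `sampling_rate_hz`, `gravity_unit_vector` and `axes` (3x3 matrix whose
#'   columns are the AP, ML, RC directions in the sensor frame).
#' @export
align_axes <- function(vel, gravity_unit_vector = NULL) {
  g <- gravity_unit_vector %||% attr(vel, "gravity_unit_vector")
  if (is.null(g)) abort("gravity_unit_vector not supplied")
  if (abs(sqrt(sum(g^2)) - 1) > 1e-6) abort("gravity vector must have unit norm")
  V <- as.matrix(vel[, c("vx", "vy", "vz")])
  v_rc <- drop(V %*% g)
  Vp <- V - outer(v_rc, g)                     # gravity-orthogonal component
  if (sum(apply(Vp, 2, var)) < 1e-18) abort("degenerate recording")
  ev <- eigen(stats::cov(Vp), symmetric = TRUE)
  ap <- ev$vectors[, 1]
  ap <- ap - sum(ap * g) * g                   # enforce exact orthogonality
  ap <- ap / sqrt(sum(ap^2))
  v_ap <- drop(V %*% ap)
  # sign convention: largest-distance excursion positive (towards target)
  b <- zero_cross_bounds(v_ap)
  if (nrow(b) > 0) {
    d <- vapply(seq_len(nrow(b)), function(i) {
      sum(v_ap[b$start[i]:(b$end[i] - 1L)])
    }, numeric(1))
    if (d[which.max(abs(d))] < 0) {
      ap <- -ap
      v_ap <- -v_ap
    }
  }
  ml <- c(g[2] * ap[3] - g[3] * ap[2],         # ML = RC x AP
          g[3] * ap[1] - g[1] * ap[3],
          g[1] * ap[2] - g[2] * ap[1])
  v_ml <- drop(V %*% ml)
  out <- tibble(time_s = vel$time_s, v_ap = v_ap, v_ml = v_ml, v_rc = v_rc)
  attr(out, "sampling_rate_hz") <- attr(vel, "sampling_rate_hz")
  attr(out, "gravity_unit_vector") <- g
  attr(out, "axes") <- cbind(AP = ap, ML = ml, RC = g)
  out
}

#' Full preprocessing chain: raw recording to body-axis velocity
#'
#' Convenience wrapper running [remove_gravity_and_lowpass()],
#' [integrate_and_bandpass()] and [align_axes()] with their defaults.
#'
#' @inheritParams remove_gravity_and_lowpass
#' @param low_hz,high_hz Band-pass edges for the velocity filter.
#' @return Body-axis velocity tibble (see [align_axes()]).
#' @export
#' @examples
#' rec <- simulate_participant(sim_params(task_duration_s = 10))
#' vel <- compute_velocity(rec$recording[[1]])
compute_velocity <- function(recording, cutoff_hz = 20, low_hz = 0.1,
                             high_hz = 20, order = 6,
                             sampling_rate_hz = NULL) {
  recording %>%
    remove_gravity_and_lowpass(cutoff_hz = cutoff_hz, order = order,
                               sampling_rate_hz = sampling_rate_hz) %>%
    integrate_and_bandpass(low_hz = low_hz, high_hz = high_hz,
                           order = order) %>%
    align_axes()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
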