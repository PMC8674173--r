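# Shared fixtures: short simulations keep the unit tests fast; the
# acceptance tests use full-length defaults.

quick_params <- function(..., task_duration_s = 10, seed = 1L) {
  sim_params(..., task_duration_s = task_duration_s, seed = seed)
}

# Random smooth one-axis velocity series (band-limited noise).
random_smooth_series <- function(n = 512, fs = 128, knots = 24) {
  x <- seq(0, 1, length.out = knots)
  y <- rnorm(knots)
  stats::spline(x, y, xout = seq(0, 1, length.out = n))$y
}

# Brute-force segmentation oracle for series without exact zeros: scan
# every consecutive sample pair for a sign change.
brute_force_bounds <- function(v) {
  n <- length(v)
  stopifnot(all(v != 0))
  starts <- 1L
  for (i in seq_len(n - 1)) {
    if (sign(v[i]) != sign(v[i + 1])) starts <- c(starts, i + 1L)
  }
  data.frame(start = starts, end = c(starts[-1], n + 1L))
}

# Minimum-jerk velocity lobe sampled at fs.
min_jerk_lobe <- function(duration_s, distance_m, fs = 128) {
  n <- max(2L, round(duration_s * fs))
  tau <- seq(0, 1, length.out = n)
  (distance_m / duration_s) * 30 * tau^2 * (1 - tau)^2
}

# A tiny element tibble with constructed metrics.
toy_elements <- function(distance, duration, hand = "right", axis = "AP",
                         t0 = seq_along(distance)) {
  tibble::tibble(
    participant_id = "P001", visit_id = "V1", hand = hand, axis = axis,
    start_time_s = t0, duration_s = duration,
    signed_distance_m = distance, distance_m = abs(distance),
    mean_speed_ms = abs(distance) / duration
  )
}
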