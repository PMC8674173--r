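make_recording <- function(A, fs = 128) {
  rec <- tibble::tibble(time_s = (seq_len(nrow(A)) - 1) / fs,
                        ax = A[, 1], ay = A[, 2], az = A[, 3])
  attr(rec, "sampling_rate_hz") <- fs
  rec
}

test_that("constant input (pure gravity) filters to zero and stores the gravity direction", {
  g <- c(1.2, -0.4, 9.7)
  A <- matrix(rep(g, each = 1024), ncol = 3)
  out <- remove_gravity_and_lowpass(make_recording(A))
  expect_lt(max(abs(as.matrix(out[, 2:4]))), 1e-9)
  expect_equal(attr(out, "gravity_unit_vector"), g / sqrt(sum(g^2)),
               tolerance = 1e-12)
})

test_that("low-pass passband gain at 1 Hz is within 1% of unity and output is zero-mean", {
  fs <- 128
  t <- (0:4095) / fs
  x <- sin(2 * pi * 1 * t)
  A <- cbind(x + 3, x, x - 5)
  out <- remove_gravity_and_lowpass(make_recording(A, fs))
  mid <- 1000:3000
  # amplitude via least squares on the quadrature pair
  amp <- function(y) {
    b <- coef(lm(y[mid] ~ sin(2 * pi * t[mid]) + cos(2 * pi * t[mid]) - 1))
    sqrt(sum(b^2))
  }
  expect_equal(amp(out$ax), 1, tolerance = 0.01)
  expect_lt(abs(mean(out$ax)) / sd(out$ax), 1e-9)
})

test_that("stopband attenuation matches the closed-form Butterworth magnitude", {
  # zero-phase filtering applies |H|^2; at fs = 2048 Hz the bilinear
  # warping at 30 Hz is negligible, so the analog formula
  # |H| = 1 / sqrt(1 + (f/fc)^(2*order)) is an independent oracle.
  fs <- 2048
  f0 <- 30
  t <- (0:16383) / fs
  x <- sin(2 * pi * f0 * t)
  out <- remove_gravity_and_lowpass(make_recording(cbind(x, x, x), fs),
                                    cutoff_hz = 20, order = 6)
  mid <- 4000:12000
  b <- coef(lm(out$ax[mid] ~ sin(2 * pi * f0 * t[mid]) +
                 cos(2 * pi * f0 * t[mid]) - 1))
  measured <- sqrt(sum(b^2))
  expected <- 1 / (1 + (f0 / 20)^12)       # |H|^2, analytic
  expect_equal(measured, expected, tolerance = 0.1)
})

test_that("too-short recordings are rejected", {
  A <- matrix(rnorm(30), ncol = 3)
  expect_error(remove_gravity_and_lowpass(make_recording(A)), "warm-up")
  expect_error(remove_gravity_and_lowpass(make_recording(matrix(rnorm(3072), ncol = 3)),
                                          cutoff_hz = 80), "Nyquist")
})

test_that("trapezoidal integration is exact for constant and bounded for ramp acceleration", {
  fs <- 128
  n <- 1024
  a <- 0.7
  acc <- tibble::tibble(time_s = (0:(n - 1)) / fs,
                        ax = rep(a, n), ay = rep(0, n), az = rep(0, n))
  attr(acc, "sampling_rate_hz") <- fs
  V <- pracma::cumtrapz(acc$ax)[, 1] / fs
  expect_equal(V, a * (0:(n - 1)) / fs, tolerance = 1e-12)

  # linear ramp a(t) = c t integrates to c t^2 / 2 within O(dt^2)
  cc <- 2.0
  tt <- (0:(n - 1)) / fs
  Vr <- pracma::cumtrapz(cc * tt)[, 1] / fs
  expect_lt(max(abs(Vr - cc * tt^2 / 2)), cc / fs^2)
})

test_that("zero acceleration integrates and filters to zero velocity", {
  n <- 1024
  acc <- tibble::tibble(time_s = (0:(n - 1)) / 128,
                        ax = rep(0, n), ay = rep(0, n), az = rep(0, n))
  attr(acc, "sampling_rate_hz") <- 128
  attr(acc, "gravity_unit_vector") <- c(0, 0, 1)
  out <- integrate_and_bandpass(acc)
  expect_lt(max(abs(as.matrix(out[, 2:4]))), 1e-12)
})

test_that("band-pass is near-idempotent on an in-band sinusoid", {
  fs <- 128
  t <- (0:4095) / fs
  x <- sin(2 * pi * 2 * t)
  bf <- signal::butter(3, c(0.1, 20) / (fs / 2), type = "pass")
  once <- signal::filtfilt(bf, x)
  twice <- signal::filtfilt(bf, once)
  mid <- 1000:3000
  expect_equal(max(abs(twice[mid])), max(abs(once[mid])), tolerance = 0.02)
})

test_that("axis alignment recovers a known rotation within 2 degrees", {
  withr::local_seed(5)
  fs <- 128
  n <- 2560
  t <- (0:(n - 1)) / fs
  # body-frame velocity: dominant AP, weaker ML, small RC
  vb <- cbind(0.5 * sin(2 * pi * 0.5 * t),
              0.08 * sin(2 * pi * 0.9 * t + 1),
              0.05 * sin(2 * pi * 1.3 * t))
  ax <- c(1, 2, -1) / sqrt(6)
  th <- 0.4
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  vs <- vb %*% t(R)
  vel <- tibble::tibble(time_s = t, vx = vs[, 1], vy = vs[, 2], vz = vs[, 3])
  attr(vel, "sampling_rate_hz") <- fs
  out <- align_axes(vel, gravity_unit_vector = R[, 3])
  ap_est <- attr(out, "axes")[, "AP"]
  ang <- acos(min(1, abs(sum(ap_est * R[, 1])))) * 180 / pi
  expect_lt(ang, 2)
  # identity case: already in body axes
  vel2 <- tibble::tibble(time_s = t, vx = vb[, 1], vy = vb[, 2], vz = vb[, 3])
  attr(vel2, "sampling_rate_hz") <- fs
  out2 <- align_axes(vel2, gravity_unit_vector = c(0, 0, 1))
  expect_equal(abs(sum(attr(out2, "axes")[, "AP"] * c(1, 0, 0))), 1,
               tolerance = 1e-6)
})

test_that("rotation preserves total variance and pure-gravity motion errors", {
  withr::local_seed(6)
  n <- 1024
  t <- (0:(n - 1)) / 128
  vs <- cbind(0.3 * sin(2 * pi * 0.7 * t), 0.1 * cos(2 * pi * 1.1 * t),
              0.2 * sin(2 * pi * 0.4 * t + 0.3))
  vel <- tibble::tibble(time_s = t, vx = vs[, 1], vy = vs[, 2], vz = vs[, 3])
  attr(vel, "sampling_rate_hz") <- 128
  g <- c(0.3, -0.1, 0.9)
  g <- g / sqrt(sum(g^2))
  out <- align_axes(vel, gravity_unit_vector = g)
  v_in <- sum(apply(vs, 2, var))
  v_out <- sum(apply(as.matrix(out[, 2:4]), 2, var))
  expect_equal(v_out, v_in, tolerance = 1e-9)

  vg <- outer(sin(2 * pi * t), g)       # motion purely along gravity
  velg <- tibble::tibble(time_s = t, vx = vg[, 1], vy = vg[, 2], vz = vg[, 3])
  attr(velg, "sampling_rate_hz") <- 128
  expect_error(align_axes(velg, gravity_unit_vector = g), "degenerate")
})

test_that("filtering before or after alignment gives the same result", {
  withr::local_seed(7)
  fs <- 128
  n <- 2048
  t <- (0:(n - 1)) / fs
  vs <- cbind(0.4 * sin(2 * pi * 0.5 * t) + 0.02 * rnorm(n),
              0.1 * sin(2 * pi * 0.8 * t) + 0.02 * rnorm(n),
              0.05 * sin(2 * pi * 1.2 * t) + 0.02 * rnorm(n))
  g <- c(0, 0, 1)
  bf <- signal::butter(3, c(0.1, 20) / (fs / 2), type = "pass")
  filt <- apply(vs, 2, function(col) signal::filtfilt(bf, col))
  mk <- function(M) {
    v <- tibble::tibble(time_s = t, vx = M[, 1], vy = M[, 2], vz = M[, 3])
    attr(v, "sampling_rate_hz") <- fs
    v
  }
  a1 <- align_axes(mk(filt), gravity_unit_vector = g)       # filter then align
  ax1 <- attr(a1, "axes")
  rot <- vs %*% ax1                                         # align then filter
  filt2 <- apply(rot, 2, function(col) signal::filtfilt(bf, col))
  expect_equal(as.matrix(a1[, 2:4]), filt2, tolerance = 1e-9,
               ignore_attr = TRUE)
})
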