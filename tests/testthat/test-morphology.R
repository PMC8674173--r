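test_that("normalized profiles have length 60 and unit mean", {
  withr::local_seed(51)
  for (i in 1:20) {
    p <- abs(rnorm(sample(2:200, 1))) + 0.01
    s <- normalize_element(p)
    expect_length(s, 60)
    expect_equal(mean(s), 1, tolerance = 1e-9)
  }
  # negative lobes are flipped to non-negative shapes
  s <- normalize_element(-min_jerk_lobe(0.5, 0.2))
  expect_true(all(s >= 0))
  expect_error(normalize_element(c(0.5)), "2 samples")
  expect_error(normalize_element(c(1, -1)), "zero mean")
})

test_that("minimum-jerk lobes at different scales normalize to identical shapes", {
  # densely sampled so the linear-resampling error is below the tolerance
  a <- normalize_element(min_jerk_lobe(0.5, 0.2, fs = 20480))
  b <- normalize_element(min_jerk_lobe(1.5, 0.05, fs = 20480))
  c <- normalize_element(min_jerk_lobe(0.25, 0.45, fs = 20480))
  expect_equal(a, b, tolerance = 1e-6)
  expect_equal(a, c, tolerance = 1e-6)
})

test_that("60-sample resampling error is below the fine-grid interpolation bound", {
  # oracle: evaluate the analytic shape densely and bound the linear
  # interpolation error of a 200-sample source resampled to 60
  tau200 <- seq(0, 1, length.out = 200)
  src <- 30 * tau200^2 * (1 - tau200)^2
  got <- normalize_element(src)
  truth <- hoff_reference(60)
  # max curvature of 30 t^2(1-t)^2 is 60 at the ends; h = 1/199
  bound <- 60 * (1 / 199)^2 / 8 + 1e-6
  expect_lt(max(abs(got - truth)), bound * 2)
})

test_that("Hoff reference is the unit-mean minimum-jerk profile", {
  h <- hoff_reference(61)
  expect_equal(max(h) * mean(30 * seq(0, 1, length.out = 61)^2 *
                               (1 - seq(0, 1, length.out = 61))^2),
               1.875, tolerance = 1e-9)   # peak 30/16 before renormalization
  expect_equal(mean(h), 1, tolerance = 1e-9)
  expect_equal(h, rev(h))                  # symmetric
  expect_equal(profile_r2(h, h), 1)
  expect_error(hoff_reference(2), ">= 3")
})

test_that("leave-one-subject-out PCA gives orthonormal loadings and recovers planted structure", {
  withr::local_seed(52)
  base <- hoff_reference(60)
  u1 <- sin(2 * pi * seq(0, 1, length.out = 60))
  u2 <- cos(2 * pi * seq(0, 1, length.out = 60))
  profiles <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), each = 30),
    shape = lapply(1:180, function(i) {
      base + rnorm(1, 0, 0.5) * u1 + rnorm(1, 0, 0.25) * u2 +
        rnorm(60, 0, 1e-4)
    })
  )
  res <- loso_pca(profiles, held_out = "P01")
  W <- res$basis$rotation
  expect_equal(crossprod(W), diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  # 2-component reconstruction residual is at the planted noise floor
  X <- do.call(rbind, profiles$shape[profiles$participant_id == "P01"])
  Xc <- sweep(X, 2, res$basis$center)
  resid <- Xc - (Xc %*% W) %*% t(W)
  expect_lt(sqrt(mean(resid^2)), 5e-4)
})

test_that("the held-out participant cannot influence the fitted basis", {
  withr::local_seed(53)
  profiles <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:5), each = 10),
    shape = lapply(1:50, function(i) abs(rnorm(60)) + 0.1)
  )
  r1 <- loso_pca(profiles, held_out = "P03")
  mutated <- profiles
  idx <- which(mutated$participant_id == "P03")
  mutated$shape[idx] <- lapply(idx, function(i) rep(99, 60))
  r2 <- loso_pca(mutated, held_out = "P03")
  expect_identical(r1$basis, r2$basis)
})

test_that("half-test deltas are zero for identical halves and detect planted convergence", {
  base <- hoff_reference(60)
  skewed <- normalize_element(dbeta(seq(0.001, 0.999, length.out = 60), 2, 5))
  mk_scores <- function(pid, shapes1, shapes2) {
    n1 <- length(shapes1)
    n2 <- length(shapes2)
    tibble::tibble(
      participant_id = pid, visit_id = "V1", hand = "right",
      axis = "AP",
      start_time_s = c(seq(1, 18, length.out = n1),
                       seq(21, 38, length.out = n2)),
      duration_s = 0.2,
      shape = c(shapes1, shapes2),
      pc1 = c(rnorm(n1, 0, 2), rnorm(n2, 0, 0.5)),
      pc2 = rnorm(n1 + n2)
    )
  }
  withr::local_seed(54)
  # planted: distorted first half, near-Hoff second half (small
  # per-participant jitter so group deltas are not degenerate)
  sc <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:6), function(pid) {
    w <- runif(1, 0.7, 1)
    mk_scores(pid,
              shapes1 = rep(list(w * skewed + (1 - w) * base), 10),
              shapes2 = rep(list(base), 10))
  }))
  htc <- half_test_comparison(sc)
  expect_true(all(htc$deltas$delta_r2_hoff > 0))
  r <- dplyr::filter(tidy(htc), metric == "delta_sd_pc1")
  expect_lt(r$estimate, 0)

  # identical halves: all deltas zero, t = 0, p = 1
  sc0 <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:4), function(pid) {
    s <- mk_scores(pid, rep(list(base), 8), rep(list(base), 8))
    s$pc1 <- rep(c(-1, 1), 8)
    s$pc2 <- rep(c(-2, 2), 8)
    s
  }))
  htc0 <- half_test_comparison(sc0)
  expect_true(all(abs(htc0$deltas$delta_sd_pc1) < 1e-12))
  t0 <- dplyr::filter(tidy(htc0), metric == "delta_sd_pc1")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
})

test_that("participant-hands with too few elements in a half are skipped with a warning", {
  base <- hoff_reference(60)
  sc <- tibble::tibble(
    participant_id = "P01", visit_id = "V1", hand = "right", axis = "AP",
    start_time_s = c(1, 2, 3, 25), duration_s = 0.2,
    shape = rep(list(base), 4), pc1 = rnorm(4), pc2 = rnorm(4)
  )
  expect_warning(htc <- half_test_comparison(sc), "skipping")
  expect_equal(nrow(htc$deltas), 0)
})

test_that("synthetic healthy cohorts converge in the second half while severe cohorts do not", {
  mk <- function(sev, g, n, s0) {
    dplyr::bind_rows(lapply(1:n, function(i) {
      simulate_participant(sim_params(severity = sev, group = g,
                                      seed = s0 + i),
                          participant_id = sprintf("%s%02d", g, i))
    }))
  }
  healthy <- mk(0, "healthy", 10, 500)
  severe <- mk(20, "ataxia", 10, 600)
  meta <- dplyr::distinct(dplyr::bind_rows(healthy["participant_id"],
                                           severe["participant_id"]))
  run <- function(cohort) {
    sc <- morphology_scores(decompose_cohort(cohort))
    md <- dplyr::distinct(cohort[, c("participant_id", "group")])
    dplyr::filter(tidy(half_test_comparison(sc, metadata = md)),
                  metric == "delta_sd_pc1")
  }
  rh <- run(healthy)
  rs <- run(severe)
  expect_lt(rh$p_value, 0.05)
  expect_lt(rh$estimate, 0)
  expect_gt(rs$p_value, 0.05)
})
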