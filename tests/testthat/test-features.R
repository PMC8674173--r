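test_that("aggregation matches hand-computed values and handles singletons", {
  a <- aggregate_stats(c(1, 2, 3, 4))
  expect_equal(unname(a["mean"]), 2.5)
  expect_equal(unname(a["median"]), 2.5)
  expect_equal(unname(a["range"]), 3)
  # type-7 order statistics, computed by hand: p10 = 1 + 0.3 * 1
  expect_equal(unname(a["p10"]), 1.3)
  expect_equal(unname(a["p90"]), 3.7)
  expect_equal(unname(a["iqr"]), 3.25 - 1.75)

  s <- aggregate_stats(5)
  expect_equal(unname(s["mean"]), 5)
  expect_equal(unname(s["sd"]), 0)
  expect_equal(unname(s["range"]), 0)
  expect_equal(unname(s["iqr"]), 0)
  expect_error(aggregate_stats(numeric(0)), "empty")
})

test_that("aggregation is permutation invariant", {
  withr::local_seed(41)
  x <- rnorm(37)
  expect_identical(aggregate_stats(x), aggregate_stats(sample(x)))
})

test_that("size/speed/duration features follow log identities", {
  el <- toy_elements(distance = c(0.1, 0.2, 0.4, 0.15, 0.3),
                     duration = c(0.3, 0.5, 0.7, 0.4, 0.6))
  f <- size_speed_duration_features(el)
  expect_length(f, 27)
  expect_equal(unname(f["logdist_mean"]), mean(log(el$distance_m)))

  el2 <- el
  el2$distance_m <- 2 * el$distance_m
  el2$mean_speed_ms <- el2$distance_m / el2$duration_s
  f2 <- size_speed_duration_features(el2)
  expect_equal(unname(f2["logdist_mean"] - f["logdist_mean"]), log(2))
  expect_equal(unname(f2["logdist_sd"]), unname(f["logdist_sd"]))

  # identical elements: all spread statistics are zero
  el3 <- toy_elements(distance = rep(0.2, 4), duration = rep(0.5, 4))
  f3 <- size_speed_duration_features(el3)
  expect_equal(unname(f3[c("dur_sd", "logdist_range", "logspeed_iqr")]),
               c(0, 0, 0))
})

test_that("power-law fit recovers exact exponents and matches a closed-form oracle", {
  D <- c(0.05, 0.1, 0.2, 0.4)
  el <- toy_elements(distance = D, duration = rep(1, 4))
  el$mean_speed_ms <- 2 * D^(2 / 3)
  expect_equal(fit_power_law(el)$alpha, 2 / 3, tolerance = 1e-12)

  el$mean_speed_ms <- rep(0.3, 4)          # flat speeds: slope 0
  expect_equal(fit_power_law(el)$alpha, 0, tolerance = 1e-12)

  withr::local_seed(42)
  eln <- toy_elements(distance = runif(40, 0.01, 0.4), duration = rep(1, 40))
  eln$mean_speed_ms <- eln$distance_m^0.5 * exp(rnorm(40, 0, 0.2))
  x <- log(eln$distance_m)
  y <- log(eln$mean_speed_ms)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit_power_law(eln)$alpha, beta, tolerance = 1e-10)

  el_deg <- toy_elements(distance = rep(0.1, 3), duration = c(1, 2, 3))
  expect_error(fit_power_law(el_deg), "degenerate")
})

test_that("transition histogram is a probability distribution with correct placement", {
  # strict alternation of large +/- 0.4 m elements: all mass pairs large
  # distances, none in the small region
  el <- toy_elements(distance = rep(c(0.4, -0.4), 10), duration = 0.5)
  th <- transition_features(el)
  expect_equal(sum(th$probabilities), 1)
  expect_equal(unname(sum(th$features)), 0)
  expect_equal(th$n_pairs, 19)

  # all tiny elements: small-region mass is 1
  el2 <- toy_elements(distance = rep(c(0.005, -0.005), 8), duration = 0.05)
  th2 <- transition_features(el2)
  expect_equal(unname(sum(th2$features)), 1)
  # alternation: mass sits in the (neg,pos) and (pos,neg) sign cells
  expect_equal(unname(th2$features[["trans_np"]] +
                        th2$features[["trans_pn"]]), 1, tolerance = 1e-12)

  withr::local_seed(43)
  el3 <- toy_elements(distance = rnorm(60, 0, 0.1), duration = 0.2)
  expect_equal(sum(transition_features(el3)$probabilities), 1)

  # single element per hand: zero features with a warning
  expect_warning(th4 <- transition_features(toy_elements(0.1, 0.5)),
                 "transition features")
  expect_equal(unname(sum(th4$features)), 0)
})

test_that("pairs are formed within hands, not across them", {
  left <- toy_elements(distance = c(0.005, 0.006), duration = 0.1,
                       hand = "left", t0 = c(1, 2))
  right <- toy_elements(distance = c(0.4, -0.4), duration = 0.5,
                        hand = "right", t0 = c(1, 2))
  th <- transition_features(dplyr::bind_rows(left, right))
  expect_equal(th$n_pairs, 2)   # one pair per hand
  expect_equal(unname(sum(th$features)), 0.5)
})

test_that("consecutive ratio features reduce to known log-ratios", {
  el <- toy_elements(distance = c(0.1, 0.2), duration = 0.5)
  f <- consecutive_ratio_features(el)
  expect_equal(unname(f["ratio_mean"]), log(2))
  expect_equal(unname(f["ratio_sd"]), 0)

  el2 <- toy_elements(distance = rep(0.25, 6), duration = 0.5)
  expect_equal(unname(consecutive_ratio_features(el2)["ratio_sd"]), 0)

  # hand-computed three-element stream
  el3 <- toy_elements(distance = c(0.1, 0.4, 0.2), duration = 0.5)
  lr <- c(log(4), log(0.5))
  expect_equal(unname(consecutive_ratio_features(el3)["ratio_mean"]),
               mean(lr))
})

test_that("feature vector has the documented 53 entries and is reproducible", {
  withr::local_seed(44)
  el <- toy_elements(distance = rnorm(80, 0, 0.15),
                     duration = runif(80, 0.05, 0.8), t0 = 1:80)
  el$distance_m <- abs(el$signed_distance_m) + 1e-4
  el$mean_speed_ms <- el$distance_m / el$duration_s
  scores <- tibble::tibble(pc1 = rnorm(80), pc2 = rnorm(80))
  v1 <- build_feature_vector(el, scores)
  v2 <- build_feature_vector(el, scores)
  expect_length(v1, 53)
  expect_identical(v1, v2)
  expect_false(anyNA(v1))
  expect_error(build_feature_vector(el, NULL), "morphology")

  # dropping the exclusion list gives the full 59
  v3 <- build_feature_vector(el, scores, exclusions = character(0))
  expect_length(v3, 59)
})

test_that("feature extraction is invariant to the ordering of hands", {
  cohort <- simulate_participant(quick_params(seed = 45))
  el <- decompose_cohort(cohort)
  el_rev <- dplyr::arrange(el, dplyr::desc(hand), start_time_s)
  f1 <- extract_features(el)
  f2 <- extract_features(el_rev)
  fc <- setdiff(names(f1), c("participant_id", "visit_id"))
  expect_equal(as.numeric(f1[1, fc]), as.numeric(f2[1, fc]),
               tolerance = 1e-12)
})
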