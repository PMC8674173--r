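#' Simulation parameters for a synthetic finger-to-nose recording
#'
#' Builds the parameter list that drives [simulate_participant()]. The
#' defaults emulate the instrumented finger-to-nose test (FNT): a seated
#' participant reaching repeatedly between their nose and a tablet target
#' about 0.45 m away, recorded by a wrist accelerometer at 128 Hz for 40 s
#' per hand, with the target switching sides every 10 s.
#'
#' Severity is expressed on a 0-30 scale (a BARS analogue). With increasing
#' severity the generator splits each reach into more sub-lobes with
#' lognormally shrinking distances, injects direction reversals near the
#' endpoint (dysmetria), skews and multi-peaks the velocity-lobe shapes, and
#' lowers the speed-distance power-law exponent linearly from 2/3 at
#' severity 0 to `alpha_floor` at severity 30. The parkinsonism group is
#' slow and small but smooth: one lobe per reach, no extra reversals.
#'
#' @param sampling_rate_hz Sampling rate of the simulated accelerometer (Hz).
#' @param task_duration_s Task length per hand (s).
#' @param reach_distance_m Nose-to-target distance along the anteroposterior
#'   (AP) axis (m).
#' @param target_switch_s Interval at which the on-screen target switches
#'   sides (s); flips the sign of the mediolateral (ML) component.
#' @param severity Severity on the synthetic 0-30 BARS-analogue scale. Must
#'   be 0 for the healthy group.
#' @param group One of `"healthy"`, `"ataxia"`, `"parkinsonism"`.
#' @param pediatric_flag Pediatric participant; reach amplitude is scaled by
#'   `pediatric_scale` (shorter arms).
#' @param noise_sd_ms2 White accelerometer noise SD (m/s^2).
#' @param seed Integer seed; identical parameters give bit-identical output.
#' @param speed_gain Power-law gain `k` in `vbar = k * D^alpha` (SI units).
#' @param alpha_floor Generating power-law exponent at severity 30; the
#'   exponent falls linearly from 2/3 at severity 0.
#' @param alpha_anchor_m Distance (m) at which mean speed is held fixed as
#'   the exponent drops: `vbar = k * anchor^(2/3) * (D / anchor)^alpha`.
#'   Reaches far above the anchor therefore slow down with severity while
#'   small corrective movements keep near-healthy speeds.
#' @param ml_distance_m,rc_distance_m Typical ML / rostrocaudal (RC)
#'   excursions accompanying each reach (m).
#' @param split_rate Poisson rate multiplier for severity-driven splitting of
#'   a reach into sub-lobes (expected extra lobes at severity 30).
#' @param reversal_rate Poisson rate multiplier for severity-driven
#'   endpoint reversal pairs (dysmetria) at severity 30.
#' @param settle_rate_ap,settle_rate Poisson means of small post-reach
#'   settling lobes on the AP axis and on each of ML/RC (present at all
#'   severities; models physiological corrections, mostly postural and so
#'   concentrated off the reaching axis). Both scale up, and settle size
#'   shrinks, with severity (dysmetric oscillation).
#' @param shape_sd_base,shape_sd_severity Lognormal SD of the Beta-shape
#'   parameters of each velocity lobe at severity 0 and the extra SD added
#'   at severity 30 (controls skew/irregularity of profiles).
#' @param optimize_shapes If `TRUE`, participants with severity < 8 tighten
#'   their lobe shapes towards the minimum-jerk profile in the second half
#'   of the task (within-task motor optimization).
#' @param fatigue_factor For participants whose optimization is impaired
#'   (severity >= 8, or `optimize_shapes = FALSE` with severity > 0),
#'   second-half shape variability instead grows by
#'   `1 + fatigue_factor * severity / 30` (mild fatigue).
#' @param pediatric_scale Amplitude multiplier applied when
#'   `pediatric_flag` is `TRUE`.
#' @param rotation_sd_deg SD of the random sensor-mount rotation angle
#'   (degrees) between body and sensor frames.
#' @param park_amp_scale,park_speed_scale Amplitude and speed multipliers
#'   for the parkinsonism group.
#'
#' @return A named list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(severity = 12, group = "ataxia", seed = 1)
#' rec <- simulate_participant(p)
sim_params <- function(sampling_rate_hz = 128,
                       task_duration_s = 40,
                       reach_distance_m = 0.45,
                       target_switch_s = 10,
                       severity = 0,
                       group = c("healthy", "ataxia", "parkinsonism"),
                       pediatric_flag = FALSE,
                       noise_sd_ms2 = 0.03,
                       seed = 1L,
                       speed_gain = 1.0,
                       alpha_floor = 0.4,
                       alpha_anchor_m = 0.02,
                       ml_distance_m = 0.06,
                       rc_distance_m = 0.12,
                       split_rate = 3.0,
                       reversal_rate = 3.0,
                       settle_rate = 2.2,
                       settle_rate_ap = 0.5,
                       shape_sd_base = 0.45,
                       shape_sd_severity = 0.7,
                       optimize_shapes = TRUE,
                       fatigue_factor = 0.35,
                       pediatric_scale = 0.8,
                       rotation_sd_deg = 6,
                       park_amp_scale = 0.75,
                       park_speed_scale = 0.55) {
  group <- match.arg(group)
  p <- list(
    sampling_rate_hz = sampling_rate_hz, task_duration_s = task_duration_s,
    reach_distance_m = reach_distance_m, target_switch_s = target_switch_s,
    severity = severity, group = group, pediatric_flag = pediatric_flag,
    noise_sd_ms2 = noise_sd_ms2, seed = as.integer(seed),
    speed_gain = speed_gain, alpha_floor = alpha_floor,
    alpha_anchor_m = alpha_anchor_m,
    ml_distance_m = ml_distance_m, rc_distance_m = rc_distance_m,
    split_rate = split_rate, reversal_rate = reversal_rate,
    settle_rate = settle_rate, settle_rate_ap = settle_rate_ap,
    shape_sd_base = shape_sd_base,
    shape_sd_severity = shape_sd_severity, optimize_shapes = optimize_shapes,
    fatigue_factor = fatigue_factor,
    pediatric_scale = pediatric_scale, rotation_sd_deg = rotation_sd_deg,
    park_amp_scale = park_amp_scale, park_speed_scale = park_speed_scale
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$sampling_rate_hz > 0, p$task_duration_s > 0,
            p$reach_distance_m > 0, p$target_switch_s > 0,
            p$noise_sd_ms2 >= 0)
  n <- p$sampling_rate_hz * p$task_duration_s
  if (abs(n - round(n)) > 1e-9) {
    abort("sampling_rate_hz * task_duration_s must be an integer sample count")
  }
  if (p$severity < 0 || p$severity > 30) {
    abort("severity must lie in [0, 30]")
  }
  if (p$group == "healthy" && p$severity != 0) {
    abort("severity must be 0 for the healthy group")
  }
  invisible(p)
}

# Unit-mean velocity-lobe shape on [0, 1]: a Beta density or a two-Beta
# mixture (any density on [0, 1] integrates to 1, so the sampled profile has
# unit mean speed by construction).
lobe_shape_fun <- function(shape) {
  if (is.null(shape$w)) {
    function(tau) dbeta(tau, shape$p, shape$q)
  } else {
    function(tau) {
      shape$w * dbeta(tau, shape$p, shape$q) +
        (1 - shape$w) * dbeta(tau, shape$p2, shape$q2)
    }
  }
}

# Draw a lobe shape; sigma controls lognormal jitter of the Beta parameters
# around the minimum-jerk value (p = q = 3), pm the multi-peak probability.
draw_shape <- function(sigma, pm) {
  # parameters are clamped above 1 so the density stays finite at the edges
  cl <- function(x) pmax(1.1, x)
  if (runif(1) < pm) {
    list(p = cl(2 * rlnorm(1, 0, sigma)), q = cl(5 * rlnorm(1, 0, sigma)),
         p2 = cl(5 * rlnorm(1, 0, sigma)), q2 = cl(2 * rlnorm(1, 0, sigma)),
         w = runif(1, 0.35, 0.65))
  } else {
    list(p = cl(3 * rlnorm(1, 0, sigma)), q = cl(3 * rlnorm(1, 0, sigma)),
         w = NULL)
  }
}

# One goal-directed movement on one body axis: main sub-lobe train covering
# `distance` in direction `dir`, then dysmetric reversal pairs, then small
# settling lobes. Returns list(lobes = tibble, t_end).
axis_movement <- function(distance, dir, t0, p, sev_frac, alpha_gen,
                          speed_scale, split, second_half,
                          settle_rate) {
  shape_sigma <- p$shape_sd_base + p$shape_sd_severity * sev_frac
  pm <- 0.2 + 0.35 * sev_frac
  if (second_half) {
    if (p$optimize_shapes && p$severity < 8) {
      # within-task motor optimization: shapes converge to minimum jerk
      shape_sigma <- 0.04
      pm <- 0.01
    } else {
      # impaired optimization plus mild fatigue: shape variability drifts
      # up instead of converging
      shape_sigma <- shape_sigma * (1 + p$fatigue_factor * sev_frac)
    }
  }
  n_sub <- if (split) 1L + rpois(1, p$split_rate * sev_frac) else 1L
  w <- exp(-0.7 * (seq_len(n_sub) - 1)) * rlnorm(n_sub, 0, 0.4)
  d_sub <- distance * w / sum(w)

  n_rev <- if (split) rpois(1, 0.05 + p$reversal_rate * sev_frac^2) else
    rpois(1, 0.05)
  d_rev <- if (n_rev > 0) {
    rlnorm(n_rev, log(0.012 * (1 - 0.25 * sev_frac)), 0.5)
  } else numeric(0)

  n_set <- rpois(1, settle_rate * (1 + 3.5 * sev_frac^2))
  d_set <- if (n_set > 0) {
    rlnorm(n_set, log(0.004 * (1 - 0.35 * sev_frac)), 0.6)
  } else numeric(0)

  dist <- c(d_sub, rep(d_rev, each = 2), d_set)
  sign_rev <- as.vector(rbind(rep(-1, n_rev), rep(1, n_rev)))
  sgn <- c(rep(1, n_sub), sign_rev,
           if (n_set > 0) (-1)^seq_len(n_set) else numeric(0)) * dir

  a0 <- p$alpha_anchor_m
  vbar <- speed_scale * p$speed_gain * a0^(2 / 3) *
    (dist / a0)^alpha_gen * rlnorm(length(dist), 0, 0.1)
  dur <- pmin(pmax(dist / vbar, 0.06), 2.5)
  gap <- runif(length(dist), 0.02, 0.10) + 0.05 * sev_frac
  gap[1] <- 0
  t_start <- t0 + cumsum(gap) + cumsum(c(0, head(dur, -1)))
  shapes <- lapply(seq_along(dist), function(i) draw_shape(shape_sigma, pm))
  list(
    lobes = tibble(
      t_start = t_start, dur = dur, vbar = vbar * sgn, dist = dist,
      shape = shapes
    ),
    t_end = if (length(dist)) max(t_start + dur) else t0
  )
}

# Evaluate scheduled lobes onto the fixed sampling grid (velocity in m/s).
render_lobes <- function(lobes, n, fs) {
  v <- numeric(n)
  for (i in seq_len(nrow(lobes))) {
    i0 <- max(1L, floor(lobes$t_start[i] * fs) + 1L)
    i1 <- min(n, ceiling((lobes$t_start[i] + lobes$dur[i]) * fs) + 1L)
    if (i0 > n || i1 < i0) next
    idx <- i0:i1
    tau <- ((idx - 1) / fs - lobes$t_start[i]) / lobes$dur[i]
    keep <- tau >= 0 & tau <= 1
    f <- lobe_shape_fun(lobes$shape[[i]])
    v[idx[keep]] <- v[idx[keep]] + lobes$vbar[i] * f(tau[keep])
  }
  v
}

# Body-frame velocity (n x 3: AP, ML, RC) for one hand.
simulate_hand_velocity <- function(p) {
  fs <- p$sampling_rate_hz
  n <- as.integer(round(fs * p$task_duration_s))
  sev_frac <- p$severity / 30
  alpha_gen <- 2 / 3 - (2 / 3 - p$alpha_floor) * sev_frac
  amp <- if (p$pediatric_flag) p$pediatric_scale else 1
  speed_scale <- 1
  split <- TRUE
  if (p$group == "parkinsonism") {
    amp <- amp * p$park_amp_scale
    speed_scale <- p$park_speed_scale
    sev_frac <- 0
    alpha_gen <- 2 / 3
    split <- FALSE
  }

  lobes <- vector("list", 512)
  k <- 0L
  t <- runif(1, 0.2, 0.5)
  dir <- 1   # +1 = towards the tablet
  while (t < p$task_duration_s - 0.3) {
    second_half <- t >= p$task_duration_s / 2
    side <- if ((t %/% p$target_switch_s) %% 2 == 0) 1 else -1
    d_ap <- amp * p$reach_distance_m * rlnorm(1, 0, 0.05)
    d_ml <- amp * p$ml_distance_m * rlnorm(1, 0, 0.3)
    d_rc <- amp * p$rc_distance_m * rlnorm(1, 0, 0.3)
    mv_ap <- axis_movement(d_ap, dir, t, p, sev_frac, alpha_gen,
                           speed_scale, split, second_half,
                           p$settle_rate_ap)
    mv_ml <- axis_movement(d_ml, side * dir, t + runif(1, 0, 0.05), p,
                           sev_frac, alpha_gen, speed_scale, split,
                           second_half, p$settle_rate)
    mv_rc <- axis_movement(d_rc, -dir, t + runif(1, 0, 0.05), p,
                           sev_frac, alpha_gen, speed_scale, split,
                           second_half, p$settle_rate)
    t_end <- max(mv_ap$t_end, mv_ml$t_end, mv_rc$t_end)
    if (t_end > p$task_duration_s - 0.1) break  # movement would be truncated
    lobes[[k + 1L]] <- mutate(mv_ap$lobes, axis = 1)
    lobes[[k + 2L]] <- mutate(mv_ml$lobes, axis = 2)
    lobes[[k + 3L]] <- mutate(mv_rc$lobes, axis = 3)
    k <- k + 3L
    t <- t_end + runif(1, 0.12, 0.30) * (1 + 0.5 * sev_frac)
    dir <- -dir
  }
  if (k == 0L) return(matrix(0, n, 3))
  lobes <- bind_rows(lobes[seq_len(k)])
  vapply(1:3, function(a) {
    render_lobes(lobes[lobes$axis == a, ], n, fs)
  }, numeric(n))
}

# Small random rotation matrix (sensor mount misalignment).
random_rotation <- function(sd_deg) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- rnorm(1, 0, sd_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Simulate one participant's two-hand finger-to-nose recording
#'
#' Generates body-frame velocity as a schedule of Beta-shaped velocity lobes
#' whose mean speed follows `vbar = k * D^alpha`, differentiates to
#' acceleration, rotates into a randomly misaligned sensor frame, adds
#' gravity (9.81 m/s^2 along the body rostrocaudal axis, rotated with the
#' frame) and white sensor noise, and samples at `sampling_rate_hz`.
#'
#' @param params A [sim_params()] list.
#' @param participant_id,visit_id Identifiers stored in the output.
#' @param dominant_hand `"right"` or `"left"`.
#' @param rater_sd SD of the rater noise added to severity before rounding
#'   to half points to form `clinical_score` (BARS granularity). For the
#'   parkinsonism group the clinical score is a UPDRS-like value on a
#'   different scale and is not derived from `severity`.
#' @return A tibble with one row per hand: participant metadata plus a
#'   `recording` list-column of tibbles (`time_s`, `ax`, `ay`, `az` in
#'   m/s^2, sensor frame, gravity present) with attribute
#'   `sampling_rate_hz`.
#' @export
simulate_participant <- function(params, participant_id = "P001",
                                 visit_id = "V1", dominant_hand = "right",
                                 rater_sd = 1.0) {
  validate_sim_params(params)
  withr::with_seed(params$seed, {
    fs <- params$sampling_rate_hz
    n <- as.integer(round(fs * params$task_duration_s))
    R <- random_rotation(params$rotation_sd_deg)
    g <- c(0, 0, 9.81)
    score <- if (params$group == "parkinsonism") {
      round(runif(1, 10, 50))
    } else {
      min(30, max(0, round(2 * (params$severity + rnorm(1, 0, rater_sd))) / 2))
    }
    recs <- lapply(c("left", "right"), function(hand) {
      v <- simulate_hand_velocity(params)          # n x 3 body frame
      a <- apply(v, 2, function(col) pracma::gradient(col, 1 / fs))
      a_s <- t(R %*% (t(a) + g)) +
        matrix(rnorm(3 * n, 0, params$noise_sd_ms2), n, 3)
      rec <- tibble(
        time_s = (seq_len(n) - 1) / fs,
        ax = a_s[, 1], ay = a_s[, 2], az = a_s[, 3]
      )
      attr(rec, "sampling_rate_hz") <- fs
      rec
    })
    tibble(
      participant_id = participant_id, visit_id = visit_id,
      group = params$group, severity = params$severity,
      clinical_score = score, pediatric_flag = params$pediatric_flag,
      dominant_hand = dominant_hand, hand = c("left", "right"),
      recording = recs
    )
  })
}

#' Simulate a finger-to-nose cohort
#'
#' @param n_healthy,n_ataxia,n_parkinsonism Group sizes (>= 0).
#' @param severity_range Range of the uniform severity draw for the ataxia
#'   group (BARS-analogue points).
#' @param pediatric_fraction Fraction of ataxia participants flagged
#'   pediatric.
#' @param repeat_visits Number of ataxia participants receiving a second
#'   visit (severity drifts by `N(0, visit_drift_sd)`, clamped to [0, 30]).
#' @param visit_drift_sd SD of the between-visit severity drift.
#' @param rater_sd Rater noise SD passed to [simulate_participant()].
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @param params Baseline [sim_params()] whose non-severity settings apply
#'   to every participant.
#' @return A tibble with one row per participant-visit-hand (two hands per
#'   visit) and a `recording` list-column; metadata columns as in
#'   [simulate_participant()].
#' @export
#' @examples
#' cohort <- simulate_cohort(2, 2, 0, seed = 7)
#' dplyr::count(cohort, group)
simulate_cohort <- function(n_healthy, n_ataxia, n_parkinsonism = 0,
                            severity_range = c(3, 24),
                            pediatric_fraction = 0.15,
                            repeat_visits = 0, visit_drift_sd = 1.0,
                            rater_sd = 1.0, seed = 1L,
                            params = sim_params()) {
  stopifnot(n_healthy >= 0, n_ataxia >= 0, n_parkinsonism >= 0,
            repeat_visits <= n_ataxia)
  total <- n_healthy + n_ataxia + n_parkinsonism
  if (total == 0) return(tibble())
  withr::with_seed(as.integer(seed), {
    groups <- rep(c("healthy", "ataxia", "parkinsonism"),
                  c(n_healthy, n_ataxia, n_parkinsonism))
    sev <- numeric(total)
    sev[groups == "ataxia"] <- runif(n_ataxia, severity_range[1],
                                     severity_range[2])
    ped <- rep(FALSE, total)
    ped[groups == "ataxia"] <- runif(n_ataxia) < pediatric_fraction
    dom <- ifelse(runif(total) < 0.9, "right", "left")
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    revisit <- rep(FALSE, total)
    if (repeat_visits > 0) {
      revisit[which(groups == "ataxia")[seq_len(repeat_visits)]] <- TRUE
    }
    drift <- rnorm(total, 0, visit_drift_sd)
    seeds2 <- sample.int(.Machine$integer.max - 1L, total)
  })
  rows <- lapply(seq_len(total), function(i) {
    pid <- sprintf("P%03d", i)
    p <- params
    p$group <- groups[i]
    p$severity <- sev[i]
    p$pediatric_flag <- ped[i]
    p$seed <- seeds[i]
    out <- simulate_participant(p, participant_id = pid, visit_id = "V1",
                                dominant_hand = dom[i], rater_sd = rater_sd)
    if (revisit[i]) {
      p2 <- p
      p2$severity <- min(30, max(0, sev[i] + drift[i]))
      p2$seed <- seeds2[i]
      out <- bind_rows(out, simulate_participant(
        p2, participant_id = pid, visit_id = "V2",
        dominant_hand = dom[i], rater_sd = rater_sd))
    }
    out
  })
  bind_rows(rows)
}

#' Write a simulated cohort to disk
#'
#' Writes one CSV per recording (`time_s, ax, ay, az`) plus a cohort
#' manifest CSV with metadata and relative file paths.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::pmap_chr(
    list(cohort$participant_id, cohort$visit_id, cohort$hand,
         cohort$recording),
    function(pid, vid, hand, rec) {
      f <- sprintf("%s_%s_%s.csv", pid, vid, hand)
      readr::write_csv(rec, file.path(dir, f))
      f
    })
  manifest <- cohort %>%
    select(-"recording") %>%
    mutate(file = files,
           sampling_rate_hz = map_dbl(cohort$recording,
                                      ~ attr(.x, "sampling_rate_hz")))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a recording CSV written by [write_cohort()]
#'
#' @param path CSV with columns `time_s, ax, ay, az`.
#' @param sampling_rate_hz Sampling rate; if `NULL`, inferred from the
#'   median timestamp step.
#' @return A recording tibble with attribute `sampling_rate_hz`.
#' @export
read_recording <- function(path, sampling_rate_hz = NULL) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time_s", "ax", "ay", "az") %in% names(rec)))
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- 1 / median(diff(rec$time_s))
  }
  attr(rec, "sampling_rate_hz") <- sampling_rate_hz
  rec
}
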