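#' Spatially and temporally normalize a movement-element velocity profile
#'
#' Negative lobes are sign-flipped, samples are divided by their mean
#' (spatial normalization), and the profile is resampled to `n_out` points
#' by linear interpolation on the normalized time axis [0, 1]; the output
#' mean is renormalized to exactly 1 after resampling.
#'
#' @param profile Numeric velocity samples of one element (>= 2 samples,
#'   non-zero mean).
#' @param n_out Output length (default 60, matching the median element
#'   duration at 128 Hz).
#' @return Numeric vector of length `n_out` with unit mean.
#' @export
#' @examples
#' normalize_element(sin(seq(0, pi, length.out = 40)))
normalize_element <- function(profile, n_out = 60) {
  if (length(profile) < 2) abort("profile needs at least 2 samples")
  if (sum(profile) < 0) profile <- -profile
  m <- mean(profile)
  if (m == 0) abort("zero mean speed: cannot normalize")
  p <- profile / m
  x <- seq(0, 1, length.out = length(p))
  out <- approx(x, p, xout = seq(0, 1, length.out = n_out))$y
  out / mean(out)
}

#' Minimum-jerk (Hoff) reference velocity profile
#'
#' The theoretically optimal bell-shaped speed profile for point-to-point
#' movements, `s(tau) = 30 tau^2 (1 - tau)^2`, sampled at `n` points on
#' [0, 1] and renormalized to unit mean. Used as the reference shape when
#' testing for within-task optimization of movement-element morphology.
#' Any unit-mean length-`n` profile can be substituted for it in
#' [half_test_comparison()].
#'
#' @param n Number of samples (>= 3, default 60).
#' @return Numeric vector of length `n`, unit mean, symmetric, single
#'   interior peak.
#' @export
hoff_reference <- function(n = 60) {
  if (n < 3) abort("n must be >= 3")
  tau <- seq(0, 1, length.out = n)
  s <- 30 * tau^2 * (1 - tau)^2
  s / mean(s)
}

#' Coefficient of determination of a profile against a reference shape
#'
#' `r2 = 1 - SS_res / SS_tot`, with SS_tot taken about the profile's mean.
#' Can be negative for profiles far from the reference.
#'
#' @param profile,reference Unit-mean numeric vectors of equal length.
#' @return A number <= 1.
#' @export
profile_r2 <- function(profile, reference) {
  stopifnot(length(profile) == length(reference))
  ss_tot <- sum((profile - mean(profile))^2)
  ss_res <- sum((profile - reference)^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

# Fit a 2-component PCA basis on a profile matrix (rows = profiles).
# Computed from the training rows only; sign convention: each loading's
# largest-magnitude coordinate is positive.
fit_pca_basis <- function(X) {
  if (nrow(X) < 2) abort("need >= 2 training profiles")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1)) {
    abort("training matrix has rank < 2")
  }
  W <- ev$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  list(center = center, rotation = W, sdev = sqrt(pmax(ev$values, 0)))
}

#' Leave-one-subject-out PCA of normalized movement elements
#'
#' Fits a 2-component PCA basis on all profiles except the held-out
#' participant's (mean-centered, covariance eigendecomposition) and
#' projects the held-out profiles onto it. The basis is recomputed from the
#' training rows alone, so the held-out participant's data cannot influence
#' it.
#'
#' @param profiles Tibble with a `shape` list-column of unit-mean
#'   length-`n` profiles and a `participant_id` column.
#' @param held_out Participant id to hold out.
#' @return List: `basis` (center, rotation, sdev) and `scores` (tibble
#'   `pc1`, `pc2` for the held-out profiles, row order preserved).
#' @export
loso_pca <- function(profiles, held_out) {
  train <- profiles$participant_id != held_out
  if (length(unique(profiles$participant_id[train])) < 2) {
    abort("need >= 2 training participants")
  }
  Xtr <- do.call(rbind, profiles$shape[train])
  basis <- fit_pca_basis(Xtr)
  Xte <- do.call(rbind, profiles$shape[!train])
  S <- sweep(Xte, 2, basis$center) %*% basis$rotation
  list(basis = basis,
       scores = tibble(pc1 = S[, 1], pc2 = S[, 2]))
}

#' Leave-one-subject-out morphology scores for a cohort element table
#'
#' Normalizes every retained element with >= `min_samples` profile samples
#' to a unit-mean 60-sample shape, then computes each participant's PC1/PC2
#' scores under a PCA basis fit on all other participants.
#'
#' @param elements Cohort element tibble from [decompose_cohort()] (needs
#'   the `profile` list-column).
#' @param n_out Profile length after resampling.
#' @param min_samples Minimum raw profile length for a morphology score.
#' @return Tibble: `participant_id`, `visit_id`, `hand`, `axis`,
#'   `start_time_s`, `duration_s`, `pc1`, `pc2`, and the normalized `shape`
#'   list-column.
#' @export
morphology_scores <- function(elements, n_out = 60, min_samples = 2) {
  el <- elements[lengths(elements$profile) >= min_samples, ]
  if (nrow(el) == 0) abort("no elements long enough for morphology scores")
  profiles <- el %>%
    select(dplyr::any_of(c("participant_id", "visit_id", "hand", "axis",
                           "start_time_s", "duration_s"))) %>%
    mutate(shape = map(el$profile, normalize_element, n_out = n_out))
  ids <- unique(profiles$participant_id)
  if (length(ids) < 3) {
    # tiny inputs: fall back to a common basis (documented; LOSO needs >= 3)
    basis <- fit_pca_basis(do.call(rbind, profiles$shape))
    S <- sweep(do.call(rbind, profiles$shape), 2, basis$center) %*%
      basis$rotation
    return(mutate(profiles, pc1 = S[, 1], pc2 = S[, 2]))
  }
  scored <- lapply(ids, function(pid) {
    res <- loso_pca(profiles, pid)
    mutate(profiles[profiles$participant_id == pid, ],
           pc1 = res$scores$pc1, pc2 = res$scores$pc2)
  })
  bind_rows(scored)
}

#' Morphology change between task halves
#'
#' For each participant-hand, compares the first and second halves of the
#' task (split at `split_time_s`) on three metrics: SD of PC1 scores, SD of
#' PC2 scores, and the mean r-squared of normalized profiles against the
#' reference shape. Deltas are second-half minus first-half; per group, a
#' one-sample t-test against zero identifies significant change. Decreasing
#' PC-score SDs and increasing r-squared indicate convergence towards the
#' optimal profile as the task progresses.
#'
#' @param scores Morphology score tibble from [morphology_scores()] (needs
#'   `shape`, `pc1`, `pc2`, `start_time_s`, `duration_s`).
#' @param reference Unit-mean reference profile ([hoff_reference()] by
#'   default).
#' @param split_time_s Boundary between halves (s), default 20.
#' @param metadata Optional tibble with `participant_id` and `group`; when
#'   given, t-tests are reported per group.
#' @param min_elements Minimum elements per half (participant-hands below
#'   it are skipped with a warning).
#' @return List of class `half_test_comparison`: `deltas` (per
#'   participant-hand `delta_sd_pc1`, `delta_sd_pc2`, `delta_r2_hoff`) and
#'   `tests` (per group and metric: t statistic, df, p-value, n).
#' @export
half_test_comparison <- function(scores, reference = hoff_reference(),
                                 split_time_s = 20, metadata = NULL,
                                 min_elements = 2) {
  scores <- mutate(scores,
                   mid_t = .data$start_time_s + .data$duration_s / 2,
                   r2 = map_dbl(.data$shape, profile_r2,
                                reference = reference))
  half_stats <- function(df) {
    tibble(sd_pc1 = sd(df$pc1), sd_pc2 = sd(df$pc2), r2 = mean(df$r2),
           n = nrow(df))
  }
  keys <- distinct(scores, .data$participant_id, .data$visit_id, .data$hand)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- filter(scores,
                .data$participant_id == keys$participant_id[i],
                .data$visit_id == keys$visit_id[i],
                .data$hand == keys$hand[i])
    first <- filter(s, .data$mid_t < split_time_s)
    second <- filter(s, .data$mid_t >= split_time_s)
    if (nrow(first) < min_elements || nrow(second) < min_elements) {
      warn(sprintf("skipping %s %s %s: a half has < %d elements",
                   keys$participant_id[i], keys$visit_id[i], keys$hand[i],
                   min_elements))
      return(NULL)
    }
    h1 <- half_stats(first)
    h2 <- half_stats(second)
    bind_cols(keys[i, ],
              tibble(delta_sd_pc1 = h2$sd_pc1 - h1$sd_pc1,
                     delta_sd_pc2 = h2$sd_pc2 - h1$sd_pc2,
                     delta_r2_hoff = h2$r2 - h1$r2))
  })
  deltas <- bind_rows(purrr::compact(rows))
  if (nrow(deltas) == 0) {
    return(structure(list(deltas = deltas,
                          tests = tibble(group = character(0),
                                         metric = character(0),
                                         statistic = numeric(0),
                                         df = numeric(0),
                                         p_value = numeric(0),
                                         estimate = numeric(0),
                                         n = integer(0))),
                     class = "half_test_comparison"))
  }
  if (!is.null(metadata)) {
    deltas <- left_join(deltas,
                        distinct(metadata, .data$participant_id,
                                 .data$group),
                        by = "participant_id")
  } else {
    deltas$group <- "all"
  }
  tests <- deltas %>%
    tidyr::pivot_longer(dplyr::all_of(c("delta_sd_pc1", "delta_sd_pc2",
                                        "delta_r2_hoff")),
                        names_to = "metric", values_to = "delta") %>%
    group_by(.data$group, .data$metric) %>%
    summarise(test = list(one_sample_t(.data$delta)), n = n(),
              .groups = "drop") %>%
    tidyr::unnest("test")
  structure(list(deltas = deltas, tests = tests),
            class = "half_test_comparison")
}
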