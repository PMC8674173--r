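# Segmentation boundaries for one velocity vector: half-open [start, end)
# index spans of single-sign runs. An exact-zero sample closes the element
# on its left (zeros are absorbed into the preceding run; leading zeros into
# the following run), so boundaries fall at every sign change between
# consecutive samples. An all-zero series yields no spans.
zero_cross_bounds <- function(v) {
  n <- length(v)
  if (n == 0) return(tibble(start = integer(0), end = integer(0)))
  s <- sign(v)
  nz <- which(s != 0)
  if (length(nz) == 0) return(tibble(start = integer(0), end = integer(0)))
  # carry the last non-zero sign forward; leading zeros take the first sign
  filled <- s
  filled[seq_len(nz[1] - 1)] <- s[nz[1]]
  last <- s[nz[1]]
  for (i in nz[1]:n) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  change <- which(filled[-1] != filled[-n]) + 1L
  starts <- c(1L, change)
  ends <- c(change, n + 1L)
  tibble(start = starts, end = ends)
}

#' Segment a one-axis velocity series into movement elements
#'
#' Boundaries are placed at every sign change between consecutive samples;
#' an exact zero sample closes the preceding element and opens the next.
#' Leading and trailing partial lobes are kept, and the spans cover the full
#' series, so segment durations sum to the series duration.
#'
#' @param velocity Numeric velocity vector for one body axis (m/s).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param time_offset_s Time of the first sample (s), used for
#'   `start_time_s`.
#' @return Tibble of elements with columns `start_index`, `end_index`
#'   (half-open), `start_time_s`, `duration_s`, `signed_distance_m`,
#'   `distance_m`, `mean_speed_ms` and a `profile` list-column of the
#'   element's velocity samples. Zero rows for an all-zero series.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 128)
#' segment_axis(sin(2 * pi * t), 128)
segment_axis <- function(velocity, sampling_rate_hz, time_offset_s = 0) {
  b <- zero_cross_bounds(velocity)
  if (nrow(b) == 0) {
    return(tibble(start_index = integer(0), end_index = integer(0),
                  start_time_s = numeric(0), duration_s = numeric(0),
                  signed_distance_m = numeric(0), distance_m = numeric(0),
                  mean_speed_ms = numeric(0), profile = list()))
  }
  profiles <- map2(b$start, b$end, ~ velocity[.x:(.y - 1L)])
  m <- map(profiles, element_metrics, sampling_rate_hz = sampling_rate_hz)
  tibble(
    start_index = b$start, end_index = b$end,
    start_time_s = time_offset_s + (b$start - 1L) / sampling_rate_hz,
    duration_s = map_dbl(m, "duration_s"),
    signed_distance_m = map_dbl(m, "signed_distance_m"),
    distance_m = map_dbl(m, "distance_m"),
    mean_speed_ms = map_dbl(m, "mean_speed_ms"),
    profile = profiles
  )
}

#' Metrics of one movement element
#'
#' Signed distance is the trapezoidal integral of the velocity profile;
#' duration is the sample count over the sampling rate; mean speed is
#' unsigned distance over duration.
#'
#' @param profile Numeric vector of the element's velocity samples (m/s).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @return List with `duration_s`, `signed_distance_m`, `distance_m`,
#'   `mean_speed_ms`.
#' @export
element_metrics <- function(profile, sampling_rate_hz) {
  n <- length(profile)
  if (n == 0) abort("empty element profile")
  duration <- n / sampling_rate_hz
  if (duration <= 0) abort("zero-duration element")
  sd_m <- if (n == 1) profile / sampling_rate_hz else
    pracma::trapz(profile) / sampling_rate_hz
  list(duration_s = duration, signed_distance_m = sd_m,
       distance_m = abs(sd_m), mean_speed_ms = abs(sd_m) / duration)
}

#' Exclude sub-threshold movement elements as sensor noise
#'
#' Removes every element strictly smaller than `min_distance_m` (default
#' 1 mm) or strictly shorter than `min_duration_s` (default 5 ms); elements
#' exactly at a threshold are retained.
#'
#' @param elements Element tibble from [segment_axis()] (any extra columns
#'   pass through).
#' @param min_distance_m,min_duration_s Exclusion thresholds.
#' @return The retained elements, with attribute `exclusion_summary`: a list
#'   with `n_excluded`, `n_total` and `excluded_duration_fraction` (share of
#'   the combined element duration removed).
#' @export
apply_exclusion <- function(elements, min_distance_m = 0.001,
                            min_duration_s = 0.005) {
  drop <- elements$distance_m < min_distance_m |
    elements$duration_s < min_duration_s
  kept <- elements[!drop, ]
  total <- sum(elements$duration_s)
  attr(kept, "exclusion_summary") <- list(
    n_excluded = sum(drop), n_total = nrow(elements),
    excluded_duration_fraction =
      if (total > 0) sum(elements$duration_s[drop]) / total else 0
  )
  kept
}

#' Decompose a body-axis velocity series into retained movement elements
#'
#' Runs [segment_axis()] independently on the AP, ML and RC axes and applies
#' the noise-exclusion rule.
#'
#' @param velocity Body-axis velocity tibble from [compute_velocity()] /
#'   [align_axes()].
#' @param min_distance_m,min_duration_s Passed to [apply_exclusion()].
#' @param exclude If `FALSE`, return all elements without the exclusion
#'   filter.
#' @return Element tibble with an `axis` column (`"AP"`, `"ML"`, `"RC"`)
#'   plus the columns of [segment_axis()].
#' @export
decompose_velocity <- function(velocity, min_distance_m = 0.001,
                               min_duration_s = 0.005, exclude = TRUE) {
  fs <- attr(velocity, "sampling_rate_hz")
  t0 <- velocity$time_s[1]
  cols <- c(AP = "v_ap", ML = "v_ml", RC = "v_rc")
  el <- imap(cols, function(col, ax) {
    mutate(segment_axis(velocity[[col]], fs, time_offset_s = t0),
           axis = ax, .before = 1)
  }) %>% bind_rows()
  if (exclude) el <- apply_exclusion(el, min_distance_m, min_duration_s)
  el
}

#' Decompose every recording of a cohort
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (or assembled from
#'   [read_recording()] with the same metadata columns).
#' @param ... Passed to [decompose_velocity()].
#' @return One tibble of retained elements across the cohort, keyed by
#'   `participant_id`, `visit_id`, `hand` and `axis`, with attribute
#'   `element_counts`: per participant-visit retained element totals.
#' @export
#' @examples
#' cohort <- simulate_cohort(1, 0, 0, seed = 1,
#'                           params = sim_params(task_duration_s = 10))
#' el <- decompose_cohort(cohort)
decompose_cohort <- function(cohort, ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    vel <- compute_velocity(cohort$recording[[i]])
    el <- decompose_velocity(vel, ...)
    mutate(el,
           participant_id = cohort$participant_id[i],
           visit_id = cohort$visit_id[i],
           hand = cohort$hand[i], .before = 1)
  })
  out <- bind_rows(rows)
  counts <- out %>%
    dplyr::count(.data$participant_id, .data$visit_id, name = "n_elements")
  attr(out, "element_counts") <- counts
  out
}

#' Write the retained-element table to CSV
#'
#' @param elements Element tibble from [decompose_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_elements <- function(elements, path) {
  keep <- intersect(c("participant_id", "visit_id", "hand", "axis",
                      "start_time_s", "duration_s", "signed_distance_m",
                      "distance_m", "mean_speed_ms"), names(elements))
  readr::write_csv(elements[, keep], path)
  invisible(path)
}
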