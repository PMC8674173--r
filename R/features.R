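#' Nine-number statistical aggregation of a value sequence
#'
#' Mean, sample SD, min, max, range, interquartile range, median and the
#' 10th/90th percentiles. Percentiles use linear interpolation between
#' order statistics (`quantile type 7`); the SD of a single value is
#' defined as 0.
#'
#' @param values Non-empty numeric vector.
#' @param prefix Optional name prefix (e.g. `"dur"` gives `dur_mean`, ...).
#' @return Named numeric vector of length 9 in the fixed order
#'   `mean, sd, min, max, range, iqr, median, p10, p90`.
#' @export
#' @examples
#' aggregate_stats(c(1, 2, 3, 4))
aggregate_stats <- function(values, prefix = NULL) {
  if (length(values) == 0) abort("cannot aggregate an empty sequence")
  if (!all(is.finite(values))) abort("values must be finite")
  q <- quantile(values, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE,
                type = 7)
  out <- c(mean = mean(values),
           sd = if (length(values) > 1) sd(values) else 0,
           min = min(values), max = max(values),
           range = max(values) - min(values),
           iqr = q[4] - q[2], median = q[3], p10 = q[1], p90 = q[5])
  if (!is.null(prefix)) names(out) <- paste(prefix, names(out), sep = "_")
  out
}

#' Size, speed and duration features (27 values)
#'
#' Aggregates element durations, natural-log distances and natural-log mean
#' speeds over the pooled retained elements of one participant-visit
#' (both hands, all axes).
#'
#' @param elements Retained element tibble.
#' @return Named numeric vector of 27 features (`dur_*`, `logdist_*`,
#'   `logspeed_*`).
#' @export
size_speed_duration_features <- function(elements) {
  if (nrow(elements) == 0) abort("no elements to aggregate")
  c(aggregate_stats(elements$duration_s, "dur"),
    aggregate_stats(log(elements$distance_m), "logdist"),
    aggregate_stats(log(elements$mean_speed_ms), "logspeed"))
}

#' Fit the speed-distance power law
#'
#' Ordinary least squares of `log(mean speed)` on `log(distance)` over a
#' participant's retained elements; the slope is the scaling exponent
#' `alpha`, which is 2/3 in unimpaired reaching and decreases with ataxia
#' severity.
#'
#' @param elements Retained element tibble (needs `distance_m`,
#'   `mean_speed_ms`; >= 2 elements with distinct distances).
#' @return Object of class `power_law_fit` with `alpha`, `intercept`,
#'   `n_points` and the fitted `model`.
#' @export
#' @examples
#' el <- tibble::tibble(distance_m = c(0.1, 0.2, 0.4),
#'                      mean_speed_ms = 2 * c(0.1, 0.2, 0.4)^(2 / 3))
#' fit_power_law(el)$alpha
fit_power_law <- function(elements) {
  if (nrow(elements) < 2) abort("need at least 2 elements")
  x <- log(elements$distance_m)
  y <- log(elements$mean_speed_ms)
  if (var(x) == 0) abort("degenerate fit: all distances equal")
  m <- lm(y ~ x)
  structure(list(alpha = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                 n_points = nrow(elements), model = m),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Speed-distance power law: alpha = %.3f (n = %d)\n",
              x$alpha, x$n_points))
  invisible(x)
}

#' Transition histogram of consecutive AP movement elements
#'
#' Normalized 2D histogram of the signed distances of temporally adjacent
#' retained elements (prior vs subsequent) on the anteroposterior axis,
#' with pairs formed within each hand. The feature values are the
#' probabilities of the central cells where both elements are small
#' (|signed distance| <= `small_threshold_m`), on a 2-by-2 sign grid by
#' default: dysmetric, corrective movement sequences concentrate mass
#' there.
#'
#' @param elements_ap AP-axis retained elements, time-ordered within hand
#'   (columns `hand`, `start_time_s`, `signed_distance_m`).
#' @param bin_width_m Histogram bin width (m).
#' @param range_m Histogram half-range (m); distances beyond it are clamped
#'   into the edge bins so probabilities still sum to 1.
#' @param small_threshold_m Half-width of the central "small movements"
#'   region (m).
#' @return List of class `transition_histogram`: `bin_edges`,
#'   `probabilities` (square matrix, prior = rows), `small_region`
#'   (logical matrix marking the central cells), `features` (named cell
#'   probabilities `trans_nn, trans_np, trans_pn, trans_pp`: prior/
#'   subsequent sign of the small cells), and `n_pairs`.
#' @export
transition_features <- function(elements_ap, bin_width_m = 0.02,
                                range_m = 0.46, small_threshold_m = 0.02) {
  edges <- seq(-range_m, range_m, by = bin_width_m)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  small <- abs(centers) <= small_threshold_m - 1e-12
  small_mat <- outer(small, small, `&`)
  feature_names <- c("trans_nn", "trans_np", "trans_pn", "trans_pp")

  pairs <- elements_ap %>%
    group_by(.data$hand) %>%
    arrange(.data$start_time_s, .by_group = TRUE) %>%
    summarise(prior = list(head(.data$signed_distance_m, -1)),
              subsequent = list(tail(.data$signed_distance_m, -1)),
              .groups = "drop")
  prior <- unlist(pairs$prior)
  subsequent <- unlist(pairs$subsequent)

  H <- matrix(0, nb, nb)
  if (length(prior) == 0) {
    warn("fewer than 2 elements per hand: transition features set to 0")
    feats <- setNames(rep(0, 4), feature_names)
  } else {
    bi <- pmin(pmax(findInterval(prior, edges, rightmost.closed = TRUE),
                    1L), nb)
    bj <- pmin(pmax(findInterval(subsequent, edges,
                                 rightmost.closed = TRUE), 1L), nb)
    for (k in seq_along(bi)) H[bi[k], bj[k]] <- H[bi[k], bj[k]] + 1
    H <- H / length(bi)
    si <- which(small)
    cells <- H[si, si, drop = FALSE]
    # row-major over (prior, subsequent): (neg,neg), (neg,pos), (pos,neg),
    # (pos,pos) for the default 2x2 region
    nm <- if (length(si) == 2) feature_names else
      paste0("trans_", rep(seq_along(si), each = length(si)), "_",
             rep(seq_along(si), times = length(si)))
    feats <- setNames(as.vector(t(cells)), nm)
  }
  structure(list(bin_edges = edges, probabilities = H,
                 small_region = small_mat, features = feats,
                 n_pairs = length(prior)),
            class = "transition_histogram")
}

#' Consecutive-distance ratio features (9 values)
#'
#' Log-ratios `log(D[i+1] / D[i])` of unsigned distances of temporally
#' adjacent retained elements within each (hand, axis) stream, pooled and
#' aggregated with [aggregate_stats()]. Their spread grows when consecutive
#' sub-movements have inconsistent sizes, a signature of segmented,
#' corrective reaching.
#'
#' @param elements Retained element tibble (columns `hand`, `axis`,
#'   `start_time_s`, `distance_m`).
#' @return Named numeric vector of 9 features (`ratio_*`).
#' @export
consecutive_ratio_features <- function(elements) {
  lr <- elements %>%
    group_by(.data$hand, .data$axis) %>%
    arrange(.data$start_time_s, .by_group = TRUE) %>%
    summarise(lr = list(diff(log(.data$distance_m))), .groups = "drop") %>%
    pull(.data$lr) %>%
    unlist()
  if (length(lr) == 0) abort("need >= 2 elements in some (hand, axis) stream")
  aggregate_stats(lr, "ratio")
}

#' Default feature-exclusion list
#'
#' Six aggregations dropped from the default feature vector so the total is
#' 53: the min and max of duration, log-distance and log-speed. These
#' extremes are pinned near the 1 mm / 5 ms exclusion thresholds or set by
#' single outlier elements and carry little severity information compared
#' with the retained p10/p90/range.
#'
#' @return Character vector of feature names.
#' @export
default_feature_exclusions <- function() {
  c("dur_min", "dur_max", "logdist_min", "logdist_max",
    "logspeed_min", "logspeed_max")
}

#' Assemble a participant-visit feature vector
#'
#' Concatenates, in documented order: 27 size/speed/duration aggregations,
#' the power-law exponent `alpha`, 9 consecutive-ratio aggregations, the
#' central transition-histogram cells (4 by default), and 18 morphology
#' aggregations (PC1 and PC2 scores), then drops the configured exclusion
#' list. The default configuration totals 53 features.
#'
#' @param elements Retained elements of one participant-visit (pooled
#'   hands and axes).
#' @param morphology_scores Tibble with `pc1`, `pc2` for this
#'   participant-visit's elements (from [morphology_scores()]).
#' @param exclusions Feature names to drop; see
#'   [default_feature_exclusions()].
#' @param ... Passed to [transition_features()].
#' @return Named numeric feature vector (default length 53).
#' @export
build_feature_vector <- function(elements, morphology_scores,
                                 exclusions = default_feature_exclusions(),
                                 ...) {
  if (is.null(morphology_scores) || nrow(morphology_scores) == 0) {
    abort("morphology scores are required")
  }
  th <- transition_features(filter(elements, .data$axis == "AP"), ...)
  v <- c(
    size_speed_duration_features(elements),
    alpha = fit_power_law(elements)$alpha,
    consecutive_ratio_features(elements),
    th$features,
    aggregate_stats(morphology_scores$pc1, "pc1"),
    aggregate_stats(morphology_scores$pc2, "pc2")
  )
  v[setdiff(names(v), exclusions)]
}

#' Extract the per-participant feature table for a cohort
#'
#' Pools each participant-visit's retained elements (optionally restricted
#' to one hand), computes leave-one-subject-out morphology PC scores, and
#' assembles one feature vector per participant-visit.
#'
#' @param elements Cohort element tibble from [decompose_cohort()].
#' @param hand `"both"` (default), `"dominant"` or `"nondominant"`;
#'   hand-specific tables support the hand-consistency analysis. Dominant
#'   hand must be supplied via `metadata` when not `"both"`.
#' @param metadata Optional tibble (`participant_id`, `visit_id`,
#'   `dominant_hand`, ...) joined onto the output.
#' @param exclusions,min_morphology_samples See [build_feature_vector()]
#'   and [morphology_scores()].
#' @param ... Passed to [transition_features()].
#' @return Tibble, one row per participant-visit: id columns, metadata, and
#'   the feature columns in fixed order.
#' @export
extract_features <- function(elements, hand = c("both", "dominant",
                                                "nondominant"),
                             metadata = NULL,
                             exclusions = default_feature_exclusions(),
                             min_morphology_samples = 2, ...) {
  hand <- match.arg(hand)
  if (hand != "both") {
    if (is.null(metadata) || !"dominant_hand" %in% names(metadata)) {
      abort("hand-specific features need metadata with dominant_hand")
    }
    dom <- distinct(metadata, .data$participant_id, .data$dominant_hand)
    elements <- elements %>%
      left_join(dom, by = "participant_id") %>%
      filter((hand == "dominant") ==
               (.data$hand == .data$dominant_hand)) %>%
      select(-"dominant_hand")
  }
  scores <- morphology_scores(elements,
                              min_samples = min_morphology_samples)
  keys <- distinct(elements, .data$participant_id, .data$visit_id)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    el <- filter(elements,
                 .data$participant_id == keys$participant_id[i],
                 .data$visit_id == keys$visit_id[i])
    sc <- filter(scores,
                 .data$participant_id == keys$participant_id[i],
                 .data$visit_id == keys$visit_id[i])
    fv <- build_feature_vector(el, sc, exclusions = exclusions, ...)
    bind_cols(keys[i, ], as_tibble(as.list(fv)))
  })
  out <- bind_rows(rows)
  if (!is.null(metadata)) {
    meta <- distinct(select(metadata,
                            dplyr::any_of(c("participant_id", "visit_id",
                                            "group", "severity",
                                            "clinical_score",
                                            "pediatric_flag",
                                            "dominant_hand"))))
    out <- left_join(out, meta, by = intersect(c("participant_id",
                                                 "visit_id"), names(meta)))
  }
  out
}
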