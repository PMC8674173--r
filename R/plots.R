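#' Plot a body-axis velocity series with element boundaries
#'
#' @param velocity Tibble from [compute_velocity()].
#' @param elements Optional element tibble from [decompose_velocity()];
#'   start times are drawn as dashed boundaries.
#' @param axes Axes to show (subset of `"AP"`, `"ML"`, `"RC"`).
#' @return A ggplot object.
#' @export
plot_velocity <- function(velocity, elements = NULL,
                          axes = c("AP", "ML", "RC")) {
  long <- velocity %>%
    tidyr::pivot_longer(dplyr::all_of(c("v_ap", "v_ml", "v_rc")),
                        names_to = "axis", values_to = "v") %>%
    mutate(axis = toupper(sub("v_", "", .data$axis))) %>%
    filter(.data$axis %in% axes)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "time (s)", y = "velocity (m/s)")
  if (!is.null(elements)) {
    b <- filter(elements, .data$axis %in% axes)
    p <- p + ggplot2::geom_vline(data = b,
                                 ggplot2::aes(xintercept = .data$start_time_s),
                                 linetype = "dashed", linewidth = 0.2,
                                 colour = "grey50")
  }
  p
}

#' @export
autoplot.transition_histogram <- function(object, ...) {
  H <- object$probabilities
  edges <- object$bin_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  df <- tidyr::expand_grid(prior = centers, subsequent = centers)
  df$probability <- as.vector(t(H))
  ggplot2::ggplot(df, ggplot2::aes(.data$prior, .data$subsequent,
                                   fill = log10(.data$probability + 1e-6))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 p") +
    ggplot2::labs(x = "prior signed distance (m)",
                  y = "subsequent signed distance (m)")
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$model$model
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_abline(slope = object$alpha,
                         intercept = object$intercept, colour = "red") +
    ggplot2::labs(x = "log distance (m)", y = "log mean speed (m/s)",
                  subtitle = sprintf("alpha = %.3f", object$alpha))
}

#' @export
autoplot.loso_estimates <- function(object, ...) {
  d <- filter(as_tibble(unclass(object)),
              .data$group %in% c("healthy", "ataxia"))
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$estimate,
                                  colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "clinical score", y = "estimated score")
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("alpha", "intercept"),
         estimate = c(x$alpha, x$intercept))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(alpha = x$alpha, r_squared = s$r.squared, n_points = x$n_points)
}

#' @export
tidy.half_test_comparison <- function(x, ...) x$tests

#' @export
tidy.transition_histogram <- function(x, ...) {
  tibble(feature = names(x$features), probability = unname(x$features),
         n_pairs = x$n_pairs)
}
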