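#' Root mean square error
#'
#' @param estimates,labels Equal-length numeric vectors.
#' @return `sqrt(mean((estimates - labels)^2))`.
#' @export
rmse <- function(estimates, labels) {
  if (length(estimates) != length(labels) || length(estimates) == 0) {
    abort("estimates and labels must have equal non-zero length")
  }
  sqrt(mean((estimates - labels)^2))
}

#' AUC by the Mann-Whitney rank relation
#'
#' Ties contribute 1/2 through midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return The area under the ROC curve.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a bootstrap percentile confidence interval
#'
#' Point estimate by the Mann-Whitney relation; 95% CI by participant-level
#' bootstrap (rows resampled with replacement; resamples with a single
#' class are redrawn), percentile method.
#'
#' @param scores,labels As in [auc_mann_whitney()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Tibble `auc`, `ci_lower`, `ci_upper`, `n_boot`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, seed = 1L, conf = 0.95) {
  labels <- as.logical(labels)
  point <- auc_mann_whitney(scores, labels)
  n <- length(scores)
  a <- (1 - conf) / 2
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      auc_mann_whitney(scores[idx], labels[idx])
    }, numeric(1))
  })
  tibble(auc = point,
         ci_lower = unname(quantile(boots, a)),
         ci_upper = unname(quantile(boots, 1 - a)),
         n_boot = n_boot)
}

#' ICC(3,1): single-rater, consistency, two-way mixed-effects
#'
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)` from the two-way ANOVA
#' mean squares (rows = subjects, columns = repeated measures), with the
#' F-based 95% confidence interval and p-value. Rows with missing measures
#' are dropped with a warning (balanced design required).
#'
#' @param measures Numeric matrix or data frame, subjects by repeated
#'   measures (k >= 2 columns, >= 2 complete subjects).
#' @param conf Confidence level (default 0.95).
#' @return Tibble `icc`, `ci_lower`, `ci_upper`, `p_value`, `n_subjects`,
#'   `k`.
#' @export
icc31 <- function(measures, conf = 0.95) {
  M <- as.matrix(measures)
  if (anyNA(M)) {
    warn("dropping subjects with incomplete measures")
    M <- M[complete.cases(M), , drop = FALSE]
  }
  n <- nrow(M)
  k <- ncol(M)
  if (n < 2 || k < 2) abort("need >= 2 subjects with >= 2 measures")
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  f_obs <- ms_r / ms_e
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  a <- 1 - conf
  fl <- f_obs / qf(1 - a / 2, df1, df2)
  fu <- f_obs * qf(1 - a / 2, df2, df1)
  tibble(icc = icc,
         ci_lower = (fl - 1) / (fl + k - 1),
         ci_upper = (fu - 1) / (fu + k - 1),
         p_value = pf(f_obs, df1, df2, lower.tail = FALSE),
         n_subjects = n, k = k)
}

#' Welch's one-way ANOVA (unequal variances)
#'
#' Wraps [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length (>= 2 groups, each of
#'   size >= 2).
#' @return Tibble `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need >= 2 groups")
  if (any(table(groups) < 2)) abort("each group needs >= 2 observations")
  ht <- oneway.test(values ~ groups, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic),
         df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
         p_value = ht$p.value)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Unequal-variance pairwise tests following a Welch ANOVA: for groups i, j
#' the statistic is `t = (m_i - m_j) / sqrt(v_i/n_i + v_j/n_j)` with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized
#' range distribution with `k` means (`p = P(q >= |t| sqrt(2))`).
#'
#' @inheritParams welch_anova
#' @param conf Confidence level for the interval (default 0.95).
#' @return Tibble, one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference), `ci_lower`, `ci_upper`, `statistic`, `df`,
#'   `p_value`.
#' @export
games_howell <- function(values, groups, conf = 0.95) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) abort("need >= 2 groups")
  if (any(table(groups) < 2)) abort("each group needs >= 2 observations")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  n <- tapply(values, groups, length)
  pairs <- utils::combn(levels(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    pval <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                   lower.tail = FALSE)
    qc <- stats::qtukey(conf, nmeans = k, df = df) / sqrt(2)
    tibble(group1 = i, group2 = j, estimate = unname(m[i] - m[j]),
           ci_lower = unname(m[i] - m[j] - qc * sqrt(se2)),
           ci_upper = unname(m[i] - m[j] + qc * sqrt(se2)),
           statistic = unname(tstat), df = unname(df), p_value = unname(pval))
  })
  bind_rows(rows)
}

#' Welch's two-sample t-test
#'
#' @param a,b Numeric samples (each length >= 2).
#' @return Tibble `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference).
#' @export
welch_t <- function(a, b) {
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, estimate = mean(a) - mean(b))
}

#' One-sample t-test against a theoretical mean
#'
#' Zero-variance samples equal to `mu` return `t = 0, p = 1` (no change,
#' by convention).
#'
#' @param x Numeric sample (length >= 2).
#' @param mu Theoretical mean (default 0).
#' @return Tibble `statistic`, `df`, `p_value`, `estimate` (sample mean).
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2) abort("need >= 2 observations")
  if (sd(x) == 0) {
    if (mean(x) == mu) {
      return(tibble(statistic = 0, df = length(x) - 1, p_value = 1,
                    estimate = mean(x)))
    }
    abort("data are constant and differ from mu: t is undefined")
  }
  ht <- t.test(x, mu = mu)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, estimate = mean(x))
}

#' Pearson correlation with test
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Tibble `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ht <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Evaluation report for a fitted pipeline run
#'
#' Bundles the regression metrics (RMSE, squared Pearson r), classification
#' AUC with bootstrap CI, test-retest ICC(3,1) when repeated visits exist,
#' and the Welch ANOVA over per-group element counts.
#'
#' @param estimates `loso_estimates` from [loso_regress()].
#' @param probabilities Optional `loso_probabilities` from
#'   [loso_classify()].
#' @param element_counts Optional tibble `participant_id`, `visit_id`,
#'   `group`, `n_elements`.
#' @param seed Seed for the AUC bootstrap.
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(estimates, probabilities = NULL,
                              element_counts = NULL, seed = 1L) {
  out <- list(regression = glance.loso_estimates(estimates))
  ev <- estimates[estimates$group %in% c("healthy", "ataxia"), ]
  out$pearson <- pearson_cor(ev$estimate, ev$label)
  if (!is.null(probabilities)) {
    out$auc <- auc_ci(probabilities$probability, probabilities$truth,
                      seed = seed)
  }
  rep_ids <- unique(ev$participant_id[duplicated(ev$participant_id)])
  if (length(rep_ids) >= 2) {
    M <- ev %>%
      filter(.data$participant_id %in% rep_ids) %>%
      group_by(.data$participant_id) %>%
      filter(n() >= 2) %>%
      summarise(v1 = .data$estimate[1], v2 = .data$estimate[2],
                .groups = "drop")
    if (nrow(M) >= 2) out$icc <- icc31(as.matrix(M[, c("v1", "v2")]))
  }
  if (!is.null(element_counts) &&
      length(unique(element_counts$group)) >= 2) {
    out$element_count_anova <- welch_anova(element_counts$n_elements,
                                           element_counts$group)
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  regression: RMSE %.2f, r^2 %.3f (n = %d)\n",
              x$regression$rmse, x$regression$r_squared, x$regression$n))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
                x$auc$auc, x$auc$ci_lower, x$auc$ci_upper))
  }
  if (!is.null(x$icc)) {
    cat(sprintf("  ICC(3,1) %.3f (95%% CI %.3f-%.3f)\n",
                x$icc$icc, x$icc$ci_lower, x$icc$ci_upper))
  }
  invisible(x)
}
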