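#' Configuration for the leave-one-subject-out Gaussian-process models
#'
#' @param noise_var White-noise variance of the GP regression (on z-scored
#'   labels).
#' @param exclude_pediatric_from_training Drop pediatric participants from
#'   every training fold (they are still estimated), avoiding immature
#'   motor patterns in the training signal.
#' @param seed Integer seed; the RBF length-scale is estimated per fold
#'   with a deterministic fold-derived seed.
#' @return List of class `model_config`.
#' @export
model_config <- function(noise_var = 0.01,
                         exclude_pediatric_from_training = TRUE,
                         seed = 1L) {
  structure(list(noise_var = noise_var,
                 exclude_pediatric = exclude_pediatric_from_training,
                 seed = as.integer(seed)),
            class = "model_config")
}

feature_columns <- function(features) {
  setdiff(names(features),
          c("participant_id", "visit_id", "group", "severity",
            "clinical_score", "pediatric_flag", "dominant_hand",
            "upper_limb_score"))
}

# Min-max scale to [0, 1] with parameters fit on the training fold;
# constant features map to 0. Test values outside [0, 1] are not clipped.
minmax_fit <- function(X) {
  list(min = apply(X, 2, min), max = apply(X, 2, max))
}
minmax_apply <- function(X, sc) {
  rng <- sc$max - sc$min
  rng[rng == 0] <- 1
  sweep(sweep(X, 2, sc$min), 2, rng, "/")
}

loso_folds <- function(features) unique(features$participant_id)

#' Leave-one-subject-out Gaussian-process regression of clinical score
#'
#' One fold per participant (all visits held out together). Per fold,
#' features are min-max scaled and labels z-scored on the training data
#' only, a Gaussian-process regression with a radial-basis-function kernel
#' is fit (kernlab), and the held-out visits are predicted on the original
#' label scale. Parkinsonism participants (labels on a different scale)
#' and, by default, pediatric participants are excluded from training but
#' still receive estimates.
#'
#' @param features Feature tibble from [extract_features()] with metadata
#'   columns (`participant_id`, `visit_id`, `clinical_score`, `group`,
#'   `pediatric_flag`).
#' @param label Column name of the training label (default
#'   `"clinical_score"`; use an upper-limb score column for the upper-limb
#'   variant).
#' @param config A [model_config()].
#' @return Object of class `loso_estimates`: tibble `participant_id`,
#'   `visit_id`, `group`, `label`, `estimate`, with attribute `fold_info`
#'   (per-fold scaling parameters, for leakage audits).
#' @export
loso_regress <- function(features, label = "clinical_score",
                         config = model_config()) {
  if (length(unique(features$participant_id)) < 3) {
    abort("need >= 3 participants for leave-one-subject-out folds")
  }
  fc <- feature_columns(features)
  X <- as.matrix(features[, fc])
  y <- features[[label]]
  train_ok <- features$group %in% c("healthy", "ataxia")
  if (config$exclude_pediatric && "pediatric_flag" %in% names(features)) {
    train_ok <- train_ok & !features$pediatric_flag
  }
  folds <- loso_folds(features)
  fold_info <- list()
  est <- rep(NA_real_, nrow(features))
  for (f in seq_along(folds)) {
    te <- features$participant_id == folds[f]
    tr <- !te & train_ok
    if (sum(tr) < 2) abort("training fold too small")
    ytr <- y[tr]
    mu <- mean(ytr)
    sdev <- sd(ytr)
    sc <- minmax_fit(X[tr, , drop = FALSE])
    fold_info[[f]] <- list(participant = folds[f], scaling = sc,
                           label_mean = mu, label_sd = sdev)
    if (sdev == 0) {              # degenerate: constant training labels
      est[te] <- mu
      next
    }
    Xtr <- minmax_apply(X[tr, , drop = FALSE], sc)
    Xte <- minmax_apply(X[te, , drop = FALSE], sc)
    fit <- withr::with_seed(config$seed + f, {
      sig <- stats::median(kernlab::sigest((ytr - mu) / sdev ~ Xtr,
                                           scaled = FALSE)[c(1, 3)])
      kernlab::gausspr(Xtr, (ytr - mu) / sdev, kernel = "rbfdot",
                       kpar = list(sigma = sig),
                       var = config$noise_var, scaled = FALSE)
    })
    est[te] <- kernlab::predict(fit, Xte)[, 1] * sdev + mu
  }
  out <- tibble(participant_id = features$participant_id,
                visit_id = features$visit_id,
                group = features$group,
                label = y, estimate = est)
  attr(out, "fold_info") <- fold_info
  class(out) <- c("loso_estimates", class(out))
  out
}

#' Leave-one-subject-out Gaussian-process classification
#'
#' Same fold structure and per-fold feature scaling as [loso_regress()],
#' with a Gaussian-process classifier (RBF kernel) returning the
#' probability of the positive class for each held-out participant-visit.
#'
#' @param features Feature tibble restricted to the two groups being
#'   compared.
#' @param positive The group treated as the positive class (default
#'   `"ataxia"`).
#' @param config A [model_config()].
#' @return Object of class `loso_probabilities`: tibble `participant_id`,
#'   `visit_id`, `group`, `truth` (logical), `probability`, with attribute
#'   `fold_info`.
#' @export
loso_classify <- function(features, positive = "ataxia",
                          config = model_config()) {
  groups <- unique(features$group)
  if (length(groups) != 2 || !positive %in% groups) {
    abort("features must contain exactly two groups incl. the positive one")
  }
  if (length(unique(features$participant_id)) < 3) {
    abort("need >= 3 participants for leave-one-subject-out folds")
  }
  fc <- feature_columns(features)
  X <- as.matrix(features[, fc])
  y <- factor(ifelse(features$group == positive, "pos", "neg"),
              levels = c("neg", "pos"))
  train_ok <- rep(TRUE, nrow(features))
  if (config$exclude_pediatric && "pediatric_flag" %in% names(features)) {
    train_ok <- !features$pediatric_flag
  }
  folds <- loso_folds(features)
  fold_info <- list()
  prob <- rep(NA_real_, nrow(features))
  for (f in seq_along(folds)) {
    te <- features$participant_id == folds[f]
    tr <- !te & train_ok
    if (length(unique(y[tr])) < 2) abort("a training fold has one class")
    sc <- minmax_fit(X[tr, , drop = FALSE])
    fold_info[[f]] <- list(participant = folds[f], scaling = sc)
    Xtr <- minmax_apply(X[tr, , drop = FALSE], sc)
    Xte <- minmax_apply(X[te, , drop = FALSE], sc)
    fit <- withr::with_seed(config$seed + f, {
      sig <- stats::median(kernlab::sigest(y[tr] ~ Xtr,
                                           scaled = FALSE)[c(1, 3)])
      kernlab::gausspr(Xtr, y[tr], kernel = "rbfdot",
                       kpar = list(sigma = sig), scaled = FALSE)
    })
    p <- kernlab::predict(fit, Xte, type = "probabilities")
    prob[te] <- p[, "pos"]
  }
  out <- tibble(participant_id = features$participant_id,
                visit_id = features$visit_id,
                group = features$group,
                truth = features$group == positive,
                probability = prob)
  attr(out, "fold_info") <- fold_info
  class(out) <- c("loso_probabilities", class(out))
  out
}

#' @export
#' @rdname tidy-movelem
tidy.loso_estimates <- function(x, ...) as_tibble(unclass(x))

#' Tidy and summarize model results
#'
#' `tidy()` returns the per-participant-visit table; `glance()` returns
#' one-row performance summaries (RMSE and squared Pearson correlation for
#' estimates, Mann-Whitney AUC for probabilities), computed on the rows
#' with non-parkinsonism labels for regression.
#'
#' @param x A `loso_estimates` or `loso_probabilities` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-movelem
NULL

#' @export
#' @rdname tidy-movelem
glance.loso_estimates <- function(x, ...) {
  ev <- x[x$group %in% c("healthy", "ataxia"), ]
  tibble(rmse = rmse(ev$estimate, ev$label),
         r_squared = cor(ev$estimate, ev$label)^2,
         n = nrow(ev))
}

#' @export
#' @rdname tidy-movelem
tidy.loso_probabilities <- function(x, ...) as_tibble(unclass(x))

#' @export
#' @rdname tidy-movelem
glance.loso_probabilities <- function(x, ...) {
  tibble(auc = auc_mann_whitney(x$probability, x$truth), n = nrow(x))
}
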