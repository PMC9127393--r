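#' Sliding-window decoder configuration
#'
#' Defaults follow the analysis convention: 50 ms windows stepped in
#' 5 ms increments from -100 to 800 ms around stimulus onset, with
#' leave-one-trial-out cross-validation and a label-permutation null.
#' The desk default of 200 permutations keeps interactive runs short;
#' `preset = "paper"` restores 1000.
#'
#' @param window_ms Window width in ms.
#' @param step_ms Step between window centres in ms.
#' @param start_ms,end_ms First and last window centre in ms.
#' @param n_permutations Label permutations for the significance
#'   threshold.
#' @param alpha Significance level of the permutation threshold.
#' @param lambda L2 regularization strength of the logistic
#'   discriminator.
#' @param preset `"desk"` or `"paper"`.
#' @return An object of class `sliding_config`.
#' @export
sliding_config <- function(window_ms = 50, step_ms = 5, start_ms = -100,
                           end_ms = 800, n_permutations = NULL, alpha = 0.05,
                           lambda = 1, preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (is.null(n_permutations)) {
    n_permutations <- if (preset == "paper") 1000L else 200L
  }
  if (window_ms <= 0 || step_ms <= 0) {
    stop("sliding_config: window_ms and step_ms must be > 0")
  }
  if (start_ms >= end_ms) stop("sliding_config: start_ms must be < end_ms")
  if (n_permutations < 1) stop("sliding_config: n_permutations must be >= 1")
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 start_ms = start_ms, end_ms = end_ms,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 lambda = lambda, cv = "loo", preset = preset),
            class = "sliding_config")
}

# Sample indices whose times fall inside a window (centre +/- width/2).
.window_samples <- function(epochs, center_ms, window_ms) {
  idx <- which(abs(epochs$time * 1000 - center_ms) <= window_ms / 2 + 1e-9)
  if (!length(idx)) {
    stop("window centred at ", center_ms, " ms lies outside the epoch")
  }
  idx
}

# Labels as a 0/1 vector: first factor level -> 0 (negative projection
# convention; 'congruent' sorts before 'incongruent').
.binary_labels <- function(labels, n_trials = NULL) {
  f <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes")
  if (!is.null(n_trials) && length(f) != n_trials) {
    stop("labels (", length(f), ") do not match the number of trials (",
         n_trials, ")")
  }
  list(y = as.integer(f) - 1L, levels = levels(f))
}

# Pool within-window samples as rows of a design matrix:
# (trials * samples) x channels, trial-major.
.window_design <- function(epochs, sample_idx) {
  d <- dim(epochs$data)
  n_s <- length(sample_idx)
  X <- matrix(aperm(epochs$data[, , sample_idx, drop = FALSE], c(3, 1, 2)),
              nrow = d[1] * n_s, ncol = d[2])
  # rows are ordered sample-fastest within trial
  list(X = X, trial = rep(seq_len(d[1]) - 1L, each = n_s), n_samples = n_s)
}

#' Train the discriminator for one time window
#'
#' Fits an L2-regularized logistic regression on all (trial, sample)
#' pairs inside the window, labelled by trial class, yielding the
#' channel weight vector that maximally separates the two classes.
#' With congruency labels the sign convention maps congruent trials to
#' negative projections and incongruent to positive.
#'
#' @param epochs An [eeg_epochs] object.
#' @param labels Two-level factor (or character) of trial classes; the
#'   first level is mapped to negative projections.
#' @param center_ms Window centre in ms.
#' @param window_ms Window width in ms.
#' @param lambda L2 regularization strength.
#' @return List of class `window_fit` with `w` (channel weights),
#'   `intercept`, `center_ms`, `window_ms`, `levels`.
#' @export
train_window <- function(epochs, labels, center_ms, window_ms = 50,
                         lambda = 1) {
  lab <- .binary_labels(labels, dim(epochs$data)[1])
  if (length(unique(lab$y)) < 2) {
    stop("train_window: both classes must be present")
  }
  idx <- .window_samples(epochs, center_ms, window_ms)
  des <- .window_design(epochs, idx)
  beta <- .ridge_logit_cpp(des$X, lab$y[des$trial + 1L], lambda)
  structure(list(w = as.vector(beta[-1]), intercept = beta[1],
                 center_ms = center_ms, window_ms = window_ms,
                 levels = lab$levels),
            class = "window_fit")
}

#' Project trials through a spatial weight vector
#'
#' Computes the single-trial discriminating component: the within-window
#' mean of `w' x(t)` (plus the trained intercept when a `window_fit` is
#' given). Negative values indicate evidence for the first class,
#' positive for the second.
#'
#' @param epochs An [eeg_epochs] object.
#' @param fit A `window_fit` from [train_window()], or a bare numeric
#'   weight vector.
#' @param center_ms,window_ms Window (taken from `fit` when omitted).
#' @param intercept Scalar added to each projection; defaults to the
#'   fitted intercept (0 for a bare weight vector).
#' @return Numeric vector, one projection per trial.
#' @export
project_window <- function(epochs, fit, center_ms = NULL, window_ms = NULL,
                           intercept = NULL) {
  if (inherits(fit, "window_fit")) {
    w <- fit$w
    if (is.null(center_ms)) center_ms <- fit$center_ms
    if (is.null(window_ms)) window_ms <- fit$window_ms
    if (is.null(intercept)) intercept <- fit$intercept
  } else {
    w <- as.numeric(fit)
    if (is.null(intercept)) intercept <- 0
    if (is.null(center_ms) || is.null(window_ms)) {
      stop("project_window: supply center_ms and window_ms with a bare ",
           "weight vector")
    }
  }
  if (length(w) != dim(epochs$data)[2]) {
    stop("project_window: weight length does not match channel count")
  }
  idx <- .window_samples(epochs, center_ms, window_ms)
  d <- dim(epochs$data)
  X <- matrix(epochs$data[, , idx, drop = FALSE], nrow = d[1])
  # columns are channel-major blocks per sample; w repeats per sample
  as.vector(X %*% rep(w, times = length(idx))) / length(idx) + intercept
}

#' Area under the ROC curve for discriminator scores
#'
#' Rank-based AUC of scores against two-level labels (probability that a
#' random second-class trial scores above a random first-class trial,
#' ties counted half).
#'
#' @param scores Numeric vector.
#' @param labels Two-level labels aligned with `scores`.
#' @return Az in `[0, 1]`.
#' @export
az_score <- function(scores, labels) {
  lab <- .binary_labels(labels)
  n1 <- sum(lab$y == 1)
  n0 <- sum(lab$y == 0)
  if (n1 == 0 || n0 == 0) stop("az_score: both classes must be present")
  r <- rank(scores)
  (sum(r[lab$y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-trial-out cross-validated Az for one window
#'
#' Every trial's projection is computed from a discriminator trained on
#' all remaining trials; Az is the ROC area of those held-out
#' projections against the labels.
#'
#' @inheritParams train_window
#' @return List with `az` and `scores` (held-out projections).
#' @export
loo_az <- function(epochs, labels, center_ms, window_ms = 50, lambda = 1) {
  lab <- .binary_labels(labels, dim(epochs$data)[1])
  if (sum(lab$y == 0) < 2 || sum(lab$y == 1) < 2) {
    stop("loo_az: need at least 2 trials per class")
  }
  idx <- .window_samples(epochs, center_ms, window_ms)
  des <- .window_design(epochs, idx)
  scores <- as.vector(.loo_decisions_cpp(des$X, lab$y[des$trial + 1L],
                                         des$trial, dim(epochs$data)[1],
                                         lambda))
  list(az = az_score(scores, labels), scores = scores)
}

#' Permutation significance threshold for decoder performance
#'
#' Shuffles the trial labels, recomputes the leave-one-out Az at the
#' given window, and returns the `1 - alpha` quantile of the null
#' distribution.
#'
#' @inheritParams train_window
#' @param n_permutations Number of label shuffles (>= 20 for a 5%
#'   quantile).
#' @param alpha Significance level.
#' @param seed Optional seed for the shuffling stream.
#' @return List with `threshold` and `null_az` (the permutation Az
#'   values).
#' @export
permutation_threshold <- function(epochs, labels, center_ms, window_ms = 50,
                                  lambda = 1, n_permutations = 200,
                                  alpha = 0.05, seed = NULL) {
  if (n_permutations < 20) {
    warning("permutation_threshold: fewer than 20 permutations gives a ",
            "coarse 5% quantile")
  }
  run <- function() {
    vapply(seq_len(n_permutations), function(p) {
      loo_az(epochs, sample(labels), center_ms, window_ms, lambda)$az
    }, numeric(1))
  }
  null_az <- if (is.null(seed)) run() else {
    .local_seed(.substream_seed(seed, "permutation"), run())
  }
  list(threshold = quantile(null_az, 1 - alpha, names = FALSE),
       null_az = null_az)
}

#' Forward model (scalp projection) of a discriminating component
#'
#' Computes `a = X y / (y' y)` where `X` stacks the within-window data
#' as channels x (trials * samples) and the trial projections `y` are
#' expanded across the window samples. `a` is the channel-space pattern
#' whose coupling with `y` best explains the observed data and is
#' interpretable as a scalp topography.
#'
#' @param epochs An [eeg_epochs] object.
#' @param y Per-trial projections (length = number of trials).
#' @param center_ms,window_ms Window definition.
#' @return Numeric channel-space vector.
#' @export
forward_model <- function(epochs, y, center_ms, window_ms = 50) {
  d <- dim(epochs$data)
  if (length(y) != d[1]) {
    stop("forward_model: y must have one value per trial")
  }
  idx <- .window_samples(epochs, center_ms, window_ms)
  des <- .window_design(epochs, idx)
  yexp <- y[des$trial + 1L]
  denom <- sum(yexp^2)
  if (denom <= 0) stop("forward_model: y has zero variance (y'y = 0)")
  as.vector(crossprod(des$X, yexp)) / denom
}

#' Sliding-window discrimination of two trial classes
#'
#' Runs the full single-trial analysis: for every window centre it
#' trains the regularized logistic discriminator, computes single-trial
#' projections, the leave-one-trial-out Az, and the forward-model scalp
#' pattern; finally it estimates the permutation significance threshold
#' at the peak-Az window.
#'
#' @param epochs An [eeg_epochs] object.
#' @param labels Two-level trial labels (first level -> negative
#'   projections).
#' @param config A [sliding_config()].
#' @param seed Seed for the permutation stream.
#' @param permutations Whether to estimate the permutation threshold.
#' @return An object of class `discriminator_result`: list with
#'   `az_curve` (data frame `center_ms`, `az`), `projections`
#'   (trials x windows), `loo_scores`, `weights` and `forward_models`
#'   (channels x windows), `threshold`, `null_az`, `config`, `levels`.
#' @export
decode_sliding <- function(epochs, labels, config = sliding_config(),
                           seed = 1, permutations = TRUE) {
  stopifnot(inherits(config, "sliding_config"))
  centers <- seq(config$start_ms, config$end_ms, by = config$step_ms)
  t_ms <- epochs$time * 1000
  ok <- centers - config$window_ms / 2 >= t_ms[1] - 1e-9 &
    centers + config$window_ms / 2 <= t_ms[length(t_ms)] + 1e-9
  if (!any(ok)) stop("decode_sliding: no window fits inside the epoch")
  centers <- centers[ok]
  d <- dim(epochs$data)
  nw <- length(centers)
  weights <- matrix(0, d[2], nw)
  fmods <- matrix(0, d[2], nw)
  proj <- matrix(0, d[1], nw)
  loo_scores <- matrix(0, d[1], nw)
  az <- numeric(nw)
  for (k in seq_len(nw)) {
    fit <- train_window(epochs, labels, centers[k], config$window_ms,
                        config$lambda)
    weights[, k] <- fit$w
    proj[, k] <- project_window(epochs, fit)
    cv <- loo_az(epochs, labels, centers[k], config$window_ms, config$lambda)
    az[k] <- cv$az
    loo_scores[, k] <- cv$scores
    fmods[, k] <- forward_model(epochs, proj[, k], centers[k],
                                config$window_ms)
  }
  thr <- NULL
  null_az <- NULL
  if (permutations) {
    peak <- centers[which.max(az)]
    pt <- permutation_threshold(epochs, labels, peak, config$window_ms,
                                config$lambda, config$n_permutations,
                                config$alpha, seed = seed)
    thr <- pt$threshold
    null_az <- pt$null_az
  }
  structure(list(az_curve = data.frame(center_ms = centers, az = az),
                 projections = proj, loo_scores = loo_scores,
                 weights = weights, forward_models = fmods,
                 threshold = thr, null_az = null_az, config = config,
                 levels = .binary_labels(labels)$levels),
            class = "discriminator_result")
}

#' @export
print.discriminator_result <- function(x, ...) {
  pk <- x$az_curve[which.max(x$az_curve$az), ]
  cat(sprintf("discriminator_result: %d windows (%g..%g ms), peak Az %.3f at %g ms\n",
              nrow(x$az_curve), min(x$az_curve$center_ms),
              max(x$az_curve$center_ms), pk$az, pk$center_ms))
  if (!is.null(x$threshold)) {
    cat(sprintf("  permutation threshold (alpha %.2f): Az %.3f\n",
                x$config$alpha, x$threshold))
  }
  invisible(x)
}

#' Locate the early and late discriminating components
#'
#' Finds the window of maximal Az inside each search interval. Ties
#' break toward the earlier window; a flat curve additionally emits a
#' warning.
#'
#' @param az_curve Data frame with `center_ms` and `az` (as in
#'   [decode_sliding()] output).
#' @param early_search,late_search Numeric `c(lo, hi)` ms intervals;
#'   must be disjoint and within the decoded range.
#' @return List with `early` and `late`, each `list(center_ms, az)`.
#' @export
find_components <- function(az_curve, early_search = c(50, 200),
                            late_search = c(250, 450)) {
  if (early_search[2] >= late_search[1]) {
    stop("find_components: search intervals must be disjoint ",
         "(early before late)")
  }
  pick <- function(interval, name) {
    sel <- az_curve$center_ms >= interval[1] & az_curve$center_ms <= interval[2]
    if (!any(sel)) {
      stop("find_components: ", name, " search interval [", interval[1], ", ",
           interval[2], "] ms contains no decoded window")
    }
    sub <- az_curve[sel, , drop = FALSE]
    if (diff(range(sub$az)) < .Machine$double.eps^0.5) {
      warning("find_components: flat Az curve in the ", name,
              " search interval; earliest window selected")
    }
    best <- which(sub$az == max(sub$az))[1]  # tie -> earlier window
    list(center_ms = sub$center_ms[best], az = sub$az[best])
  }
  list(early = pick(early_search, "early"), late = pick(late_search, "late"))
}

#' Extract per-trial component amplitudes
#'
#' For each trial, takes the projection of maximum magnitude across the
#' decoding windows whose centres fall inside the resolved early and
#' late intervals (ties toward the earlier window), stored signed and
#' absolute. The absolute values are the regressors of the
#' neurally-informed diffusion model.
#'
#' @param result A `discriminator_result` from [decode_sliding()].
#' @param early_window,late_window Numeric `c(lo, hi)` ms intervals
#'   (e.g. the component peak +/- half a window).
#' @return Data frame with `trial`, `y_early`, `y_late`, `abs_early`,
#'   `abs_late`.
#' @export
extract_amplitudes <- function(result, early_window, late_window) {
  stopifnot(inherits(result, "discriminator_result"))
  centers <- result$az_curve$center_ms
  take <- function(interval) {
    cols <- which(centers >= interval[1] & centers <= interval[2])
    if (!length(cols)) {
      stop("extract_amplitudes: no decoding window inside [", interval[1],
           ", ", interval[2], "] ms")
    }
    sub <- result$projections[, cols, drop = FALSE]
    pickcol <- max.col(abs(sub), ties.method = "first")
    sub[cbind(seq_len(nrow(sub)), pickcol)]
  }
  ye <- take(early_window)
  yl <- take(late_window)
  data.frame(trial = seq_len(nrow(result$projections)),
             y_early = ye, y_late = yl,
             abs_early = abs(ye), abs_late = abs(yl))
}
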