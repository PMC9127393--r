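#' Exclude implausibly fast and slow trials
#'
#' Removes trials with reaction times below 300 ms (fast guesses) or
#' above 1200 ms (attentional lapses). Both bounds are strict: trials at
#' exactly 300 or 1200 ms are retained. The exclusion counts by modality
#' are attached as the `"exclusions"` attribute (see
#' [exclusion_report()]).
#'
#' @param trials Trial table with an `rt_ms` column (and optionally
#'   `modality`, else inferred from `stimulus`).
#' @param min_ms,max_ms Exclusion bounds in milliseconds.
#' @return The filtered table, with an exclusion report attached.
#' @export
filter_trials <- function(trials, min_ms = 300, max_ms = 1200) {
  if (is.null(trials$rt_ms)) stop("filter_trials: trials must have rt_ms")
  if (is.null(trials$modality)) {
    trials$modality <- .stimulus_modality(trials$stimulus)
  }
  drop <- trials$rt_ms < min_ms | trials$rt_ms > max_ms
  report <- data.frame(modality = sort(unique(trials$modality)))
  report$n_excluded <- vapply(report$modality, function(m) {
    sum(drop & trials$modality == m)
  }, integer(1))
  report$n_retained <- vapply(report$modality, function(m) {
    sum(!drop & trials$modality == m)
  }, integer(1))
  out <- trials[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("filter_trials: all trials excluded")
  attr(out, "exclusions") <- report
  out
}

#' Exclusion report of a filtered trial table
#'
#' @param trials A table returned by [filter_trials()].
#' @return Data frame of excluded/retained counts by modality.
#' @export
exclusion_report <- function(trials) attr(trials, "exclusions")

#' Per-subject condition summaries of behaviour
#'
#' Median RT and proportion of correct choices for every subject x
#' condition cell, the unit of analysis for the rank tests and the
#' bootstrap confidence intervals.
#'
#' @param trials Filtered trial table.
#' @param by Grouping column, e.g. `"congruency"` or `"stimulus"`.
#' @return Data frame with `subject`, the grouping column, `n_trials`,
#'   `median_rt_ms`, `accuracy`. Cells without trials are flagged with
#'   `NA` and a warning.
#' @export
summarize_behavior <- function(trials, by = "congruency") {
  stopifnot(by %in% names(trials))
  subjects <- sort(unique(trials$subject))
  levels_by <- sort(unique(trials[[by]]))
  grid <- expand.grid(subject = subjects, level = levels_by,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- trials$subject == grid$subject[i] & trials[[by]] == grid$level[i]
    n <- sum(sel)
    data.frame(subject = grid$subject[i], level = grid$level[i], n_trials = n,
               median_rt_ms = if (n) median(trials$rt_ms[sel]) else NA_real_,
               accuracy = if (n) mean(trials$response_correct[sel]) else NA_real_)
  })
  out <- do.call(rbind, res)
  names(out)[2] <- by
  if (anyNA(out$median_rt_ms)) {
    warning("summarize_behavior: some subject x condition cells have no trials")
  }
  out[order(out$subject, out[[by]]), , drop = FALSE]
}

.rank_tie_counts <- function(r) {
  tab <- table(r)
  tab[tab > 1]
}

#' Rank tests with standardized statistics and Z/sqrt(N) effect sizes
#'
#' Wilcoxon matched-pairs signed-rank test (paired condition medians
#' across subjects) or Mann-Whitney U test (independent trial-level RT
#' sets). The standardized statistic Z uses the normal approximation
#' with a continuity correction and tie-corrected variance, so reported
#' effect sizes `Z / sqrt(N_effect)` are reproducible. `N_effect` is
#' explicit because different comparisons standardize by different
#' populations (subjects for condition medians, trial counts for
#' correct/incorrect RT comparisons).
#'
#' @param values_a,values_b Numeric vectors: paired and equal length for
#'   `"wilcoxon_signed_rank"`, independent samples for
#'   `"mann_whitney"`.
#' @param kind Test kind.
#' @param n_effect Denominator count N for the effect size.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of the
#'   location of `values_a` relative to `values_b`).
#' @return An object of class `behavior_stats`: list with `test_name`,
#'   `statistic_z`, `p_value`, `effect_size`, `n_effect`, `alternative`.
#' @export
paired_rank_test <- function(values_a, values_b,
                             kind = c("wilcoxon_signed_rank", "mann_whitney"),
                             n_effect, alternative = "two.sided") {
  kind <- match.arg(kind)
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  if (missing(n_effect) || length(n_effect) != 1 || n_effect <= 0) {
    stop("paired_rank_test: n_effect must be a single positive count")
  }
  if (kind == "wilcoxon_signed_rank") {
    if (length(values_a) != length(values_b)) {
      stop("paired_rank_test: signed-rank test requires paired vectors ",
           "of equal length")
    }
    d <- values_a - values_b
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      z <- 0
    } else {
      r <- rank(abs(d))
      w_plus <- sum(r[d > 0])
      mu <- n * (n + 1) / 4
      ties <- .rank_tie_counts(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(ties^3 - ties) / 48
      num <- w_plus - mu
      z <- if (sigma2 <= 0) 0 else (num - sign(num) * 0.5) / sqrt(sigma2)
      if (num == 0) z <- 0
    }
  } else {
    n1 <- length(values_a)
    n2 <- length(values_b)
    if (n1 == 0 || n2 == 0) stop("paired_rank_test: empty sample")
    r <- rank(c(values_a, values_b))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- .rank_tie_counts(r)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    num <- u - mu
    z <- if (sigma2 <= 0) 0 else (num - sign(num) * 0.5) / sqrt(sigma2)
    if (num == 0) z <- 0
  }
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              less = pnorm(z),
              greater = pnorm(z, lower.tail = FALSE))
  structure(list(test_name = kind, statistic_z = z, p_value = min(p, 1),
                 effect_size = z / sqrt(n_effect), n_effect = n_effect,
                 alternative = alternative),
            class = "behavior_stats")
}

#' @export
print.behavior_stats <- function(x, ...) {
  cat(sprintf("%s: Z = %.3f, p = %.4g (%s), effect size Z/sqrt(%d) = %.3f\n",
              x$test_name, x$statistic_z, x$p_value, x$alternative,
              x$n_effect, x$effect_size))
  invisible(x)
}

#' Percentile bootstrap confidence interval of a subject-level mean
#'
#' Resamples subjects (the experimental unit) with replacement and
#' returns percentile bounds of the resampled statistic. Defaults match
#' the figure convention: 1000 iterations, 95% interval of the mean.
#'
#' @param values Per-subject values (length >= 2).
#' @param n_boot Number of bootstrap iterations.
#' @param level Confidence level.
#' @param seed Optional seed for the resampling stream.
#' @param statistic Function reducing a resample to one number.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95, seed = NULL,
                         statistic = mean) {
  if (length(values) < 2) stop("bootstrap_ci: need at least 2 values")
  if (n_boot < 1) stop("bootstrap_ci: n_boot must be >= 1")
  draw <- function() {
    stats_b <- vapply(seq_len(n_boot), function(i) {
      statistic(sample(values, replace = TRUE))
    }, numeric(1))
    quantile(stats_b, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  }
  q <- if (is.null(seed)) draw() else {
    .local_seed(.substream_seed(seed, "bootstrap"), draw())
  }
  c(low = q[1], high = q[2])
}
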