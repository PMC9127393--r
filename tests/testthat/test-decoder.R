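# Epochs with a single sample per trial drawn from two Gaussian classes.
gaussian_classes <- function(n_per_class, d, delta, sigma = NULL, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  if (is.null(sigma)) sigma <- diag(d)
  L <- t(chol(sigma))
  X <- t(L %*% matrix(rnorm(d * n), d, n))
  labels <- rep(c("congruent", "incongruent"), each = n_per_class)
  X[labels == "incongruent", ] <- X[labels == "incongruent", ] +
    matrix(delta, n_per_class, d, byrow = TRUE)
  dat <- array(X, dim = c(n, d, 1))
  list(epochs = eeg_epochs(dat, time = 0, sampling_rate = 200),
       labels = factor(labels))
}

test_that("learned weights align with the closed-form discriminant direction", {
  d <- 8
  sigma <- 0.5 * diag(d) + 0.5
  delta <- c(1, -0.5, rep(0.25, d - 2))
  gc <- gaussian_classes(300, d, delta, sigma, seed = 7)
  fit <- train_window(gc$epochs, gc$labels, center_ms = 0, window_ms = 10,
                      lambda = 1)
  oracle <- solve(sigma, delta)  # Sigma^{-1} (mu1 - mu0)
  expect_gt(cosine_sim(fit$w, oracle), 0.9)
  # flipping labels reverses the projection sign
  flipped <- train_window(gc$epochs, factor(gc$labels,
                                            levels = rev(levels(gc$labels))),
                          center_ms = 0, window_ms = 10, lambda = 1)
  expect_lt(cosine_sim(fit$w, flipped$w), -0.95)
  expect_error(train_window(gc$epochs, factor(rep("congruent", 600),
                                              levels = levels(gc$labels)),
                            0, 10), "class")
})

test_that("projection is the windowed linear readout", {
  dat <- array(0, dim = c(3, 4, 5))
  dat[, 2, ] <- c(1.5, -2, 0.25)  # constant per trial on channel 2
  ep <- eeg_epochs(dat, time = seq(0, 0.02, by = 0.005), sampling_rate = 200)
  w <- c(0, 1, 0, 0)
  y <- project_window(ep, w, center_ms = 10, window_ms = 20)
  expect_equal(y, c(1.5, -2, 0.25))
  expect_equal(project_window(ep, 2 * w, center_ms = 10, window_ms = 20),
               2 * y)
})

test_that("Az equals the brute-force pairwise ROC area", {
  # worked example: class0 scores {0.1, 0.4}, class1 {0.35, 0.8}
  labels <- factor(c("congruent", "congruent", "incongruent", "incongruent"))
  expect_equal(az_score(c(0.1, 0.4, 0.35, 0.8), labels), 0.75)
  # brute force over all pairs on random score sets (with ties)
  set.seed(5)
  for (i in 1:5) {
    n0 <- sample(5:25, 1)
    n1 <- sample(5:25, 1)
    sc <- round(c(rnorm(n0), rnorm(n1, 0.5)), 1)
    lb <- factor(rep(c("a", "b"), c(n0, n1)))
    brute <- 0
    for (u in sc[lb == "b"]) {
      for (v in sc[lb == "a"]) {
        brute <- brute + (u > v) + 0.5 * (u == v)
      }
    }
    expect_equal(az_score(sc, lb), brute / (n0 * n1))
  }
  # perfectly separated projections
  expect_equal(az_score(c(-2, -1, 1, 2), labels), 1)
})

test_that("leave-one-out discrimination is exact on separable data and sane on null data", {
  gc <- gaussian_classes(15, 4, rep(3, 4), seed = 11)
  res <- loo_az(gc$epochs, gc$labels, center_ms = 0, window_ms = 10,
                lambda = 1)
  expect_equal(res$az, 1)
  expect_equal(length(res$scores), 30)
  # null labels: held-out Az stays in the chance neighbourhood on average
  set.seed(17)
  null_az <- replicate(15, {
    gc0 <- gaussian_classes(15, 4, rep(0, 4), seed = sample.int(1e6, 1))
    loo_az(gc0$epochs, gc0$labels, 0, 10, lambda = 1)$az
  })
  expect_lt(abs(mean(null_az) - 0.5), 0.12)
  expect_error(loo_az(gc$epochs[1:3], gc$labels[1:3], 0, 10), "2 trials")
})

test_that("the permutation threshold sits above chance and flags real signal", {
  gc <- gaussian_classes(20, 4, rep(1.5, 4), seed = 23)
  pt <- permutation_threshold(gc$epochs, gc$labels, center_ms = 0,
                              window_ms = 10, lambda = 1,
                              n_permutations = 40, seed = 2)
  expect_gt(pt$threshold, 0.5)
  obs <- loo_az(gc$epochs, gc$labels, 0, 10, lambda = 1)$az
  expect_gt(obs, pt$threshold)
})

test_that("the forward model is X y / (y'y)", {
  # printed toy matrices: X = [[1,2],[3,4]], y = [1,1] -> a = [1.5, 3.5]
  dat <- array(0, dim = c(2, 2, 1))
  dat[1, , 1] <- c(1, 3)
  dat[2, , 1] <- c(2, 4)
  ep <- eeg_epochs(dat, time = 0, sampling_rate = 200)
  expect_equal(forward_model(ep, c(1, 1), center_ms = 0, window_ms = 5),
               c(1.5, 3.5))
  expect_error(forward_model(ep, c(0, 0), center_ms = 0, window_ms = 5),
               "zero variance")
  # noise-free rank-1 data: x_i = a0 * y_i recovers a0 exactly and the
  # reconstruction a y' explains all variance
  a0 <- c(2, -1, 0.5)
  y <- c(1, -0.4, 0.8, 2, -1.5)
  dat1 <- array(0, dim = c(5, 3, 1))
  for (i in 1:5) dat1[i, , 1] <- a0 * y[i]
  ep1 <- eeg_epochs(dat1, time = 0, sampling_rate = 200)
  a_hat <- forward_model(ep1, y, center_ms = 0, window_ms = 5)
  expect_equal(a_hat, a0)
  recon <- outer(y, a0)
  expect_gt(1 - sum((matrix(dat1, 5, 3) - recon)^2) / sum(dat1^2), 0.99)
})

test_that("forward model at the decoded peak matches the planted pattern", {
  ts <- tiny_session(trials_per_stimulus = 20, seed = 9,
                     truth_args = list(noise_sd_uv = 4, subject_gain_sd = 0))
  ep <- ts$epochs
  fit <- train_window(ep, factor(ts$trials$congruency),
                      ts$truth$early_latency_ms, 50, lambda = 5)
  y <- project_window(ep, fit)
  a <- forward_model(ep, y, ts$truth$early_latency_ms, 50)
  expect_gt(abs(cosine_sim(a, ts$truth$early_pattern)), 0.9)
})

test_that("component search honours intervals, ties and flatness", {
  curve <- data.frame(center_ms = seq(0, 500, by = 5),
                      az = 0.5 + 0.3 * exp(-((seq(0, 500, by = 5) - 105) / 40)^2))
  comps <- find_components(curve, c(50, 200), c(250, 450))
  expect_equal(comps$early$center_ms, 105)
  # tie breaks toward the earlier window
  tied <- data.frame(center_ms = c(60, 80, 100, 300, 320, 340),
                     az = c(0.7, 0.7, 0.6, 0.55, 0.55, 0.5))
  comps2 <- find_components(tied, c(50, 150), c(250, 350))
  expect_equal(comps2$early$center_ms, 60)
  expect_equal(comps2$late$center_ms, 300)
  flat <- data.frame(center_ms = c(60, 80, 300, 320), az = 0.5)
  # flat in both search intervals: one warning per interval
  expect_warning(
    expect_warning(comps3 <- find_components(flat, c(50, 100), c(250, 350)),
                   "flat"),
    "flat")
  expect_equal(comps3$early$center_ms, 60)
  expect_error(find_components(tied, c(50, 300), c(250, 350)), "disjoint")
  expect_error(find_components(tied, c(110, 140), c(250, 350)), "no decoded")
})

test_that("amplitude extraction takes the signed maximum-magnitude projection", {
  res <- structure(list(
    az_curve = data.frame(center_ms = c(100, 105, 110, 330, 335),
                          az = rep(0.6, 5)),
    projections = rbind(c(-3, 1, 2, 0.5, -0.2),
                        c(0, 0, 0, 0, 0),
                        c(1, -4, 2, -1, 3))), class = "discriminator_result")
  amps <- extract_amplitudes(res, c(95, 115), c(325, 340))
  expect_equal(amps$y_early, c(-3, 0, -4))
  expect_equal(amps$abs_early, c(3, 0, 4))
  expect_equal(amps$y_late, c(0.5, 0, 3))
  expect_error(extract_amplitudes(res, c(500, 600), c(325, 340)), "window")
})

test_that("planted congruency and stimulus components are found at their latencies", {
  ts <- tiny_session(trials_per_stimulus = 25, seed = 19,
                     truth_args = list(subject_gain_sd = 0))
  cfg <- sliding_config(step_ms = 10, start_ms = -50, end_ms = 450,
                        n_permutations = 20, lambda = 5)
  res <- decode_sliding(ts$epochs, factor(ts$trials$congruency), cfg,
                        seed = 1, permutations = FALSE)
  comps <- find_components(res$az_curve)
  expect_lt(abs(comps$early$center_ms - ts$truth$early_latency_ms), 16)
  expect_lt(abs(comps$late$center_ms - ts$truth$late_latency_ms), 16)
  # congruent trials project negative on planted data
  amps <- extract_amplitudes(res, comps$early$center_ms + c(-25, 25),
                             comps$late$center_ms + c(-25, 25))
  cong <- ts$trials$congruency == "congruent"
  expect_lt(mean(amps$y_early[cong]), 0)
  expect_gt(mean(amps$y_early[!cong]), 0)
  # stimulus-feature contrast peaks at the planted SF latencies
  sf <- decode_sliding(ts$epochs, factor(ts$trials$stimulus), cfg,
                       seed = 1, permutations = FALSE)
  sfc <- find_components(sf$az_curve, early_search = c(50, 140),
                         late_search = c(145, 250))
  expect_lt(abs(sfc$early$center_ms - ts$truth$sf_latency_ms[1]), 16)
  expect_lt(abs(sfc$late$center_ms - ts$truth$sf_latency_ms[2]), 16)
})

test_that("Az is invariant to strictly monotone transforms of the scores", {
  set.seed(3)
  sc <- rnorm(40)
  lb <- factor(rep(c("a", "b"), 20))
  base <- az_score(sc, lb)
  expect_equal(az_score(3 * sc + 2, lb), base)
  expect_equal(az_score(exp(sc), lb), base)
  expect_equal(az_score(atan(sc), lb), base)
})
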