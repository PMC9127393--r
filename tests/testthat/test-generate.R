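test_that("epoch generation is bit-identical under one seed and consistent across subsets", {
  ts <- tiny_session(trials_per_stimulus = 4, n_blocks = 2, seed = 5)
  ts2 <- tiny_session(trials_per_stimulus = 4, n_blocks = 2, seed = 5)
  expect_identical(ts$epochs$data, ts2$epochs$data)
  expect_identical(ts$amplitudes, ts2$amplitudes)

  # generating one subject of a two-subject session reproduces its data
  two <- tiny_session(n_subjects = 2, trials_per_stimulus = 4, n_blocks = 2,
                      seed = 5)
  sub1 <- two$trials[two$trials$subject == 1, ]
  ge1 <- generate_epochs(sub1, two$truth, two$config)
  expect_equal(ge1$epochs$data,
               two$epochs$data[two$trials$subject == 1, , , drop = FALSE])
})

test_that("condition-difference topography recovers the planted early pattern", {
  # strong effect, quiet noise: the trial-averaged incongruent-minus-
  # congruent map at the early latency must align with the planted vector
  ts <- tiny_session(trials_per_stimulus = 20, seed = 9,
                     truth_args = list(noise_sd_uv = 2,
                                       congruency_effect_size = c(2, 1.5),
                                       subject_gain_sd = 0))
  idx <- which(abs(ts$epochs$time * 1000 - ts$truth$early_latency_ms) <= 25)
  avg_map <- function(cond) {
    sel <- ts$trials$congruency == cond
    apply(ts$epochs$data[sel, , idx, drop = FALSE], 2, mean)
  }
  diff_map <- avg_map("incongruent") - avg_map("congruent")
  expect_gt(cosine_sim(diff_map, ts$truth$early_pattern), 0.95)
})

test_that("pattern/channel mismatch is an error", {
  ts <- tiny_session(trials_per_stimulus = 2, seed = 2)
  bad_truth <- ground_truth(n_channels = 8, seed = 2)
  expect_error(generate_epochs(ts$trials, bad_truth, ts$config),
               "does not match")
  expect_error(generate_epochs(ts$trials[0, ], ts$truth, ts$config), "empty")
})

test_that("zero congruency effect leaves near-chance class separation", {
  ts <- tiny_session(trials_per_stimulus = 20, seed = 13,
                     truth_args = list(congruency_effect_size = c(0, 0)))
  az <- loo_az(ts$epochs, factor(ts$trials$congruency),
               center_ms = ts$truth$early_latency_ms, lambda = 5)$az
  expect_gt(az, 0.3)
  expect_lt(az, 0.7)
})

test_that("zero regression slopes give statistically identical behaviour across congruency", {
  cfg <- session_config(n_subjects = 1, n_blocks = 2,
                        trials_per_stimulus_per_block = 750,
                        stimulus_features = c("high_pitch", "low_pitch"),
                        epoch_window = c(-0.1, 0.1), n_channels = 4,
                        rng_seed = 21)
  null_coef <- list(congruent = list(boundary = c(early = 0, late = 0),
                                     ndt = c(early = 0, late = 0)),
                    incongruent = list(boundary = c(early = 0, late = 0),
                                       ndt = c(early = 0, late = 0)))
  truth <- ground_truth(n_channels = 4, seed = 21,
                        true_coefficients = null_coef,
                        true_ddm = list(
                          congruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          incongruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          subject_sd = c(drift = 0, boundary = 0, ndt = 0)))
  trials <- generate_session(cfg)
  amp <- generate_epochs(trials, truth, cfg)$amplitudes
  beh <- generate_behaviour(trials, amp, truth, cfg)
  med <- tapply(beh$rt_ms, beh$congruency, median)
  acc <- tapply(beh$response_correct, beh$congruency, mean)
  expect_lt(abs(med[["congruent"]] - med[["incongruent"]]), 30)
  expect_lt(abs(acc[["congruent"]] - acc[["incongruent"]]), 0.04)
})

test_that("a negative congruent boundary slope speeds and errs congruent choices", {
  cfg <- session_config(n_subjects = 2, n_blocks = 2,
                        trials_per_stimulus_per_block = 650,
                        stimulus_features = c("high_pitch", "low_pitch"),
                        epoch_window = c(-0.1, 0.1), n_channels = 4,
                        rng_seed = 31)
  coef <- list(congruent = list(boundary = c(early = 0, late = -0.3),
                                ndt = c(early = 0, late = 0)),
               incongruent = list(boundary = c(early = 0, late = 0),
                                  ndt = c(early = 0, late = 0)))
  truth <- ground_truth(n_channels = 4, seed = 31, true_coefficients = coef,
                        true_ddm = list(
                          congruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          incongruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          subject_sd = c(drift = 0, boundary = 0, ndt = 0)))
  trials <- generate_session(cfg)
  amp <- generate_epochs(trials, truth, cfg)$amplitudes
  beh <- generate_behaviour(trials, amp, truth, cfg)  # >5000 trials
  med <- tapply(beh$rt_ms, beh$congruency, median)
  acc <- tapply(beh$response_correct, beh$congruency, mean)
  expect_lt(med[["congruent"]], med[["incongruent"]])
  expect_lt(acc[["congruent"]], acc[["incongruent"]])
})

test_that("a positive incongruent non-decision slope shifts incongruent RTs by slope x mean amplitude", {
  slope <- 0.12
  cfg <- session_config(n_subjects = 1, n_blocks = 2,
                        trials_per_stimulus_per_block = 1000,
                        stimulus_features = c("high_pitch", "low_pitch"),
                        epoch_window = c(-0.1, 0.1), n_channels = 4,
                        rng_seed = 41)
  coef <- list(congruent = list(boundary = c(early = 0, late = 0),
                                ndt = c(early = 0, late = 0)),
               incongruent = list(boundary = c(early = 0, late = 0),
                                  ndt = c(early = slope, late = 0)))
  truth <- ground_truth(n_channels = 4, seed = 41, true_coefficients = coef,
                        true_ddm = list(
                          congruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          incongruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          subject_sd = c(drift = 0, boundary = 0, ndt = 0)))
  trials <- generate_session(cfg)
  amp <- generate_epochs(trials, truth, cfg)$amplitudes
  beh <- generate_behaviour(trials, amp, truth, cfg)
  shift_ms <- mean(beh$rt_ms[beh$congruency == "incongruent"]) -
    mean(beh$rt_ms[beh$congruency == "congruent"])
  expected_ms <- 1000 * slope *
    mean(abs(amp$amp_early[trials$congruency == "incongruent"]))
  expect_lt(abs(shift_ms - expected_ms), 0.35 * expected_ms)
})

test_that("a boundary driven non-positive by the slopes rejects the configuration", {
  cfg <- session_config(n_subjects = 1, n_blocks = 2,
                        trials_per_stimulus_per_block = 5,
                        stimulus_features = c("high_pitch", "low_pitch"),
                        epoch_window = c(-0.1, 0.1), n_channels = 4,
                        rng_seed = 51)
  coef <- list(congruent = list(boundary = c(early = 0, late = -10),
                                ndt = c(early = 0, late = 0)),
               incongruent = list(boundary = c(early = 0, late = 0),
                                  ndt = c(early = 0, late = 0)))
  truth <- ground_truth(n_channels = 4, seed = 51, true_coefficients = coef)
  trials <- generate_session(cfg)
  amp <- generate_epochs(trials, truth, cfg)$amplitudes
  expect_error(generate_behaviour(trials, amp, truth, cfg), "non-positive")
})

test_that("epoch containers round-trip through the binary/JSON format", {
  ts <- tiny_session(trials_per_stimulus = 2, n_blocks = 2, seed = 8)
  stem <- tempfile("epochs")
  write_epochs(ts$epochs, stem)
  back <- read_epochs(stem)
  expect_equal(back$data, ts$epochs$data)
  expect_equal(back$time, ts$epochs$time, tolerance = 1e-12)
  expect_equal(back$channels, ts$epochs$channels)
})
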