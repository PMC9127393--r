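make_trials <- function(rt, correct = TRUE, congruency = "congruent",
                        stimulus = "high_pitch", subject = 1) {
  data.frame(subject = subject, block = 1, trial = seq_along(rt),
             congruency = congruency, stimulus = stimulus,
             modality = ifelse(grepl("pitch", stimulus), "auditory", "visual"),
             response_correct = correct, rt_ms = rt)
}

test_that("RT exclusion bounds are strict on both sides", {
  tr <- make_trials(c(299, 300, 700, 1200, 1201))
  out <- filter_trials(tr)
  expect_equal(out$rt_ms, c(300, 700, 1200))
  rep <- exclusion_report(out)
  expect_equal(rep$n_excluded[rep$modality == "auditory"], 2L)

  # identity when all RTs are in range, and idempotence
  ok <- make_trials(c(300, 650, 1200))
  expect_equal(filter_trials(ok)$rt_ms, ok$rt_ms)
  once <- filter_trials(tr)
  expect_equal(filter_trials(once)$rt_ms, once$rt_ms)
})

test_that("exclusions are reported by modality and emptiness only warns", {
  tr <- rbind(make_trials(c(100, 400), stimulus = "high_pitch"),
              make_trials(c(2000, 500), stimulus = "small_circle"))
  out <- filter_trials(tr)
  rep <- exclusion_report(out)
  expect_equal(rep$n_excluded, c(1L, 1L))
  expect_equal(rep$n_retained, c(1L, 1L))
  expect_warning(filter_trials(make_trials(c(10, 20))), "all trials")
})

test_that("condition summaries compute medians and accuracy per subject", {
  tr <- make_trials(c(400, 600, 800, 500, 700, 900, 950, 650, 720, 820),
                    correct = c(rep(TRUE, 9), FALSE))
  s <- summarize_behavior(tr, by = "congruency")
  expect_equal(s$accuracy, 0.9)
  expect_equal(s$median_rt_ms, median(tr$rt_ms))
  s2 <- summarize_behavior(make_trials(c(400, 600, 800)), by = "congruency")
  expect_equal(s2$median_rt_ms, 600)
  # missing cells are flagged
  tr2 <- rbind(make_trials(c(400, 500), subject = 1),
               make_trials(c(450, 550), subject = 2,
                           congruency = "incongruent"))
  expect_warning(s3 <- summarize_behavior(tr2), "no trials")
  expect_true(anyNA(s3$median_rt_ms))
})

test_that("generator ground truth orders condition medians at scale", {
  # boundary reduction for congruent trials => faster congruent medians
  cfg <- session_config(n_subjects = 1, n_blocks = 2,
                        trials_per_stimulus_per_block = 650,
                        stimulus_features = c("high_pitch", "low_pitch"),
                        epoch_window = c(-0.1, 0.1), n_channels = 4,
                        rng_seed = 61)
  truth <- ground_truth(n_channels = 4, seed = 61,
                        true_ddm = list(
                          congruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          incongruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                          subject_sd = c(drift = 0, boundary = 0, ndt = 0)))
  trials <- generate_session(cfg)
  amp <- generate_epochs(trials, truth, cfg)$amplitudes
  beh <- filter_trials(generate_behaviour(trials, amp, truth, cfg))
  s <- summarize_behavior(beh, by = "congruency")
  expect_lt(s$median_rt_ms[s$congruency == "congruent"],
            s$median_rt_ms[s$congruency == "incongruent"])
})

test_that("rank-test Z matches the tie-corrected normal approximation", {
  set.seed(42)
  for (i in 1:5) {
    a <- round(rnorm(20, 600, 50))
    b <- round(rnorm(20, 620, 50))
    res <- paired_rank_test(a, b, "wilcoxon_signed_rank", n_effect = 20)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(res$effect_size, res$statistic_z / sqrt(20))

    res_mw <- paired_rank_test(a, b, "mann_whitney", n_effect = 40)
    ref_mw <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(res_mw$p_value, ref_mw$p.value, tolerance = 1e-10)
    expect_equal(res_mw$effect_size, res_mw$statistic_z / sqrt(40))
  }
})

test_that("the effect size is the Z over root-N ratio at reference values", {
  # a faster paired sample must yield a negative Z and effect size
  a <- c(601, 612, 583, 640, 555, 590, 602, 588, 570, 610)
  b <- a + c(30, 25, 40, 22, 28, 35, 27, 31, 26, 33)
  res <- paired_rank_test(a, b, "wilcoxon_signed_rank", n_effect = 20)
  expect_lt(res$statistic_z, 0)
  expect_equal(res$effect_size, res$statistic_z / sqrt(20))
  # identical samples are a zero-signal case
  same <- paired_rank_test(a, a, "wilcoxon_signed_rank", n_effect = 20)
  expect_equal(same$statistic_z, 0)
  expect_equal(same$effect_size, 0)
  expect_error(paired_rank_test(a, b, "wilcoxon_signed_rank", n_effect = 0),
               "n_effect")
  expect_error(paired_rank_test(a, b[-1], "wilcoxon_signed_rank",
                                n_effect = 20), "equal length")
})

test_that("one-sided alternatives move the p-value in the hypothesised direction", {
  a <- c(500, 520, 540, 515, 505, 530, 525, 545)
  b <- a + 25
  less <- paired_rank_test(a, b, "wilcoxon_signed_rank", n_effect = 8,
                           alternative = "less")
  greater <- paired_rank_test(a, b, "wilcoxon_signed_rank", n_effect = 8,
                              alternative = "greater")
  expect_lt(less$p_value, 0.05)
  expect_gt(greater$p_value, 0.9)
})

test_that("bootstrap intervals behave like intervals", {
  expect_equal(unname(bootstrap_ci(rep(3.5, 10), seed = 1)), c(3.5, 3.5))
  set.seed(10)
  x <- rnorm(20, 5, 2)
  ci <- bootstrap_ci(x, seed = 2)
  expect_lt(ci[["low"]], mean(x))
  expect_gt(ci[["high"]], mean(x))
  expect_error(bootstrap_ci(x, n_boot = 0), "n_boot")
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("bootstrap interval width tracks the t-based closed form", {
  set.seed(99)
  ratios <- replicate(100, {
    x <- rnorm(20)
    ci <- bootstrap_ci(x, n_boot = 400)
    t_half <- qt(0.975, 19) * sd(x) / sqrt(20)
    (ci[["high"]] - ci[["low"]]) / (2 * t_half)
  })
  expect_gt(mean(ratios), 0.7)
  expect_lt(mean(ratios), 1.3)
})

test_that("the congruency test is calibrated on null behavioural data", {
  # identical diffusion parameters in both conditions: the signed-rank
  # test on subject medians should reject at about the nominal rate
  set.seed(123)
  n_rep <- 200
  rejections <- vapply(seq_len(n_rep), function(r) {
    med <- matrix(0, 10, 2)
    for (s in 1:10) {
      for (ci in 1:2) {
        sim <- simulate_ddm(list(drift = 1.85, boundary = 1.3, ndt = 0.33),
                            n = 40)
        med[s, ci] <- median(sim$rt)
      }
    }
    paired_rank_test(med[, 1], med[, 2], "wilcoxon_signed_rank",
                     n_effect = 10)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})
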