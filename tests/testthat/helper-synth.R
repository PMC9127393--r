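# Shared builders for small synthetic datasets.

# One-subject auditory session with planted components.
tiny_session <- function(n_subjects = 1, trials_per_stimulus = 15,
                         n_blocks = 2, n_channels = 16, seed = 3,
                         epoch_window = c(-0.2, 0.6), truth_args = list()) {
  cfg <- session_config(
    n_subjects = n_subjects, n_blocks = n_blocks,
    trials_per_stimulus_per_block = trials_per_stimulus,
    stimulus_features = c("high_pitch", "low_pitch"),
    epoch_window = epoch_window, n_channels = n_channels, rng_seed = seed)
  truth <- do.call(ground_truth,
                   c(list(n_channels = n_channels, seed = seed), truth_args))
  trials <- generate_session(cfg)
  ge <- generate_epochs(trials, truth, cfg)
  list(config = cfg, truth = truth, trials = trials,
       epochs = ge$epochs, amplitudes = ge$amplitudes)
}

# Behavioural design straight from the diffusion simulator: S subjects,
# n trials each (split over the two congruency conditions), group-level
# parameters `group = c(drift, boundary, ndt)` with subject scatter, and
# optional true slopes on |amplitude| regressors.
sim_design <- function(S, n_per_subject, seed,
                       group = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                       subject_sd = c(0.15, 0.10, 0.03),
                       beta_late_congruent = 0,
                       gamma_early_incongruent = 0,
                       amp_mean = c(early = 0.8, late = 0.6),
                       amp_sd = 0.5) {
  set.seed(seed)
  half <- n_per_subject %/% 2
  rows <- vector("list", 2 * S)
  k <- 0
  for (s in seq_len(S)) {
    for (cond in c("congruent", "incongruent")) {
      v <- group[["drift"]] + rnorm(1, 0, subject_sd[1])
      a0 <- max(0.4, group[["boundary"]] + rnorm(1, 0, subject_sd[2]))
      t0 <- max(0.05, group[["ndt"]] + rnorm(1, 0, subject_sd[3]))
      e <- abs(rnorm(half, amp_mean[["early"]], amp_sd))
      l <- abs(rnorm(half, amp_mean[["late"]], amp_sd))
      a <- a0 + if (cond == "congruent") beta_late_congruent * l else 0
      tau <- t0 + if (cond == "incongruent") gamma_early_incongruent * e else 0
      sim <- simulate_ddm(list(drift = v, boundary = a, ndt = tau), n = half)
      k <- k + 1
      rows[[k]] <- data.frame(subject = s, congruency = cond,
                              trial = seq_len(half), rt_ms = sim$rt * 1000,
                              response_correct = sim$upper,
                              abs_early = e, abs_late = l,
                              true_drift = v, true_boundary = a0,
                              true_ndt = t0)
    }
  }
  df <- do.call(rbind, rows)
  build_design(df, df[, c("trial", "abs_early", "abs_late")])
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
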