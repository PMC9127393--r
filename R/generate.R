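#' Ground truth for the synthetic EEG/behaviour generator
#'
#' Bundles everything the generator plants in a dataset: smooth
#' channel-space patterns for the two congruency-discriminating
#' components and the stimulus-feature response, their latencies and
#' temporal envelopes, the signed amplitude separation that encodes
#' congruency (negative mean for congruent trials, positive for
#' incongruent, matching the classifier sign convention), the spatially
#' correlated noise model, and the diffusion-model parameters and
#' regression slopes that turn planted amplitudes into behaviour.
#'
#' Component latencies default to 105 ms (early) and 335 ms (late), with
#' stimulus-feature responses at 95 and 175 ms of opposite polarity; the
#' early/late amplitude separations (0.8, 0.6) are chosen so the early
#' component is the more discriminable of the two.
#'
#' @param n_channels Number of EEG channels the patterns live in.
#' @param seed Seed for drawing the patterns and noise covariance.
#' @param early_latency_ms,late_latency_ms Component peak latencies (ms).
#' @param sf_latency_ms Length-2 latencies (ms) of the two
#'   stimulus-feature responses (opposite polarity).
#' @param component_duration_ms FWHM of the Gaussian temporal envelope.
#' @param congruency_effect_size Length-2 `(early, late)` signed
#'   amplitude separation between conditions; 0 plants no congruency
#'   signal.
#' @param amplitude_sd Trial-to-trial SD of planted amplitudes.
#' @param sf_effect_size Amplitude of the stimulus-feature response.
#' @param gain_uv Microvolts of scalp signal per unit planted amplitude.
#' @param noise_sd_uv Marginal channel noise SD in microvolts.
#' @param noise_lengthscale Channel-index lengthscale of the spatial
#'   noise covariance (squared-exponential kernel).
#' @param noise_white_mix Fraction of spatially white noise mixed in
#'   (keeps the covariance well-conditioned).
#' @param ar_coef Temporal AR(1) coefficient of the noise.
#' @param subject_gain_sd Between-subject SD of a multiplicative gain on
#'   the planted component amplitudes.
#' @param true_ddm Per-condition diffusion parameters: a list with
#'   elements `congruent`/`incongruent`, each `c(drift, boundary, ndt)`,
#'   plus `subject_sd = c(drift, boundary, ndt)` between-subject SDs.
#' @param true_coefficients Regression slopes linking planted absolute
#'   amplitudes to the decision boundary and non-decision time: a list
#'   with elements `congruent`/`incongruent`, each a list
#'   `boundary = c(early, late)`, `ndt = c(early, late)` (boundary units
#'   and seconds per unit amplitude).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_channels = 128L,
                         seed = 1L,
                         early_latency_ms = 105,
                         late_latency_ms = 335,
                         sf_latency_ms = c(95, 175),
                         component_duration_ms = 60,
                         congruency_effect_size = c(early = 0.8, late = 0.6),
                         amplitude_sd = 0.5,
                         sf_effect_size = 0.25,
                         gain_uv = 12,
                         noise_sd_uv = 10,
                         noise_lengthscale = 5,
                         noise_white_mix = 0.2,
                         ar_coef = 0.3,
                         subject_gain_sd = 0.15,
                         true_ddm = list(
                           congruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                           incongruent = c(drift = 1.85, boundary = 1.3, ndt = 0.33),
                           subject_sd = c(drift = 0.15, boundary = 0.10, ndt = 0.03)),
                         true_coefficients = list(
                           congruent = list(boundary = c(early = 0, late = -0.3),
                                            ndt = c(early = 0, late = 0)),
                           incongruent = list(boundary = c(early = 0, late = 0),
                                              ndt = c(early = 0.06, late = 0)))) {
  if (component_duration_ms <= 0) {
    stop("ground_truth: component_duration_ms must be > 0")
  }
  for (cond in c("congruent", "incongruent")) {
    if (true_ddm[[cond]][["boundary"]] <= 0) {
      stop("ground_truth: boundary must be > 0")
    }
    if (true_ddm[[cond]][["ndt"]] < 0) stop("ground_truth: ndt must be >= 0")
  }
  if (length(congruency_effect_size) == 1) {
    congruency_effect_size <- rep(congruency_effect_size, 2)
  }
  congruency_effect_size <- setNames(as.numeric(congruency_effect_size),
                                     c("early", "late"))
  pats <- .local_seed(.substream_seed(seed, "truth"), {
    L <- .spatial_chol(n_channels, noise_lengthscale, noise_white_mix)
    draw <- function() {
      p <- as.vector(L %*% rnorm(n_channels))
      p / sqrt(sum(p^2))
    }
    list(early = draw(), late = draw(), sf = draw(), chol = L)
  })
  structure(list(early_pattern = pats$early, late_pattern = pats$late,
                 sf_pattern = pats$sf,
                 early_latency_ms = early_latency_ms,
                 late_latency_ms = late_latency_ms,
                 sf_latency_ms = sf_latency_ms,
                 component_duration_ms = component_duration_ms,
                 congruency_effect_size = congruency_effect_size,
                 amplitude_sd = amplitude_sd,
                 sf_effect_size = sf_effect_size,
                 gain_uv = gain_uv, noise_sd_uv = noise_sd_uv,
                 noise_spatial_cov = list(lengthscale = noise_lengthscale,
                                          white_mix = noise_white_mix,
                                          chol = pats$chol),
                 ar_coef = ar_coef, subject_gain_sd = subject_gain_sd,
                 true_ddm = true_ddm, true_coefficients = true_coefficients,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Cholesky factor of a unit-diagonal squared-exponential channel
# covariance mixed with white noise.
.spatial_chol <- function(n_channels, lengthscale, white_mix) {
  idx <- seq_len(n_channels)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * lengthscale^2)))
  K <- (1 - white_mix) * K + white_mix * diag(n_channels)
  t(chol(K))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d channels; early %g ms, late %g ms (FWHM %g ms)\n",
              length(x$early_pattern), x$early_latency_ms, x$late_latency_ms,
              x$component_duration_ms),
      sprintf("  congruency separation early %.2f / late %.2f, amplitude sd %.2f\n",
              x$congruency_effect_size[["early"]],
              x$congruency_effect_size[["late"]], x$amplitude_sd), sep = "")
  invisible(x)
}

.gauss_envelope <- function(time_s, latency_ms, fwhm_ms) {
  sd_s <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2)))
  exp(-(time_s - latency_ms / 1000)^2 / (2 * sd_s^2))
}

#' Generate EEG epochs with planted discriminative components
#'
#' Each epoch is spatially correlated AR(1) noise plus three planted
#' signals: the stimulus-feature response (sign set by the presented
#' feature, opposite polarity at its two latencies) and the early and
#' late congruency components, scaled by per-trial amplitudes whose sign
#' encodes congruency (negative mean for congruent trials). The planted
#' amplitudes are returned as recovery ground truth.
#'
#' @param trials Trial table from [generate_session()] (any subset of
#'   subjects/trials; per-subject random streams are derived from
#'   `config$rng_seed`, so subsets reproduce full-session values).
#' @param truth A [ground_truth()] whose patterns match
#'   `config$n_channels`.
#' @param config The [session_config()].
#' @return A list with `epochs` ([eeg_epochs]) and `amplitudes`, a data
#'   frame aligned 1:1 with `trials` holding the planted signed
#'   amplitudes (`amp_early`, `amp_late`) and the subject gain.
#' @export
generate_epochs <- function(trials, truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "session_config"))
  if (nrow(trials) == 0) stop("generate_epochs: trials is empty")
  nc <- config$n_channels
  if (length(truth$early_pattern) != nc) {
    stop("generate_epochs: pattern length (", length(truth$early_pattern),
         ") does not match n_channels (", nc, ")")
  }
  fs <- config$sampling_rate
  time <- seq(config$epoch_window[1], config$epoch_window[2], by = 1 / fs)
  ns <- length(time)
  env_e <- .gauss_envelope(time, truth$early_latency_ms, truth$component_duration_ms)
  env_l <- .gauss_envelope(time, truth$late_latency_ms, truth$component_duration_ms)
  env_s1 <- .gauss_envelope(time, truth$sf_latency_ms[1], truth$component_duration_ms)
  env_s2 <- .gauss_envelope(time, truth$sf_latency_ms[2], truth$component_duration_ms)
  L <- truth$noise_spatial_cov$chol
  phi <- truth$ar_coef
  dat <- array(0, dim = c(nrow(trials), nc, ns))
  amp <- data.frame(subject = trials$subject, trial = trials$trial,
                    amp_early = NA_real_, amp_late = NA_real_,
                    subject_gain = NA_real_)
  sgn_cong <- ifelse(trials$congruency == "congruent", -1, 1)
  # auditory: high pitch +, low pitch -; visual: small +, large -
  sgn_sf <- ifelse(trials$stimulus %in% c("high_pitch", "small_circle"), 1, -1)
  for (s in unique(trials$subject)) {
    rows <- which(trials$subject == s)
    .local_seed(.substream_seed(config$rng_seed, "epochs", s), {
      gain_s <- max(0.2, 1 + rnorm(1, 0, truth$subject_gain_sd))
      a_e <- rnorm(length(rows),
                   sgn_cong[rows] * truth$congruency_effect_size[["early"]] * gain_s,
                   truth$amplitude_sd)
      a_l <- rnorm(length(rows),
                   sgn_cong[rows] * truth$congruency_effect_size[["late"]] * gain_s,
                   truth$amplitude_sd)
      amp$amp_early[rows] <- a_e
      amp$amp_late[rows] <- a_l
      amp$subject_gain[rows] <- gain_s
      for (k in seq_along(rows)) {
        i <- rows[k]
        noise <- matrix(rnorm(nc * ns), nc, ns)
        if (phi != 0) {
          scl <- sqrt(1 - phi^2)
          for (t2 in 2:ns) {
            noise[, t2] <- phi * noise[, t2 - 1] + scl * noise[, t2]
          }
        }
        noise <- truth$noise_sd_uv * (L %*% noise)
        sig <- truth$gain_uv *
          (outer(truth$early_pattern, env_e) * a_e[k] +
           outer(truth$late_pattern, env_l) * a_l[k] +
           outer(truth$sf_pattern, env_s1 - env_s2) *
             (truth$sf_effect_size * sgn_sf[i]))
        dat[i, , ] <- noise + sig
      }
    })
  }
  info <- list(seed = config$rng_seed,
               truth = list(early_latency_ms = truth$early_latency_ms,
                            late_latency_ms = truth$late_latency_ms,
                            congruency_effect_size =
                              as.list(truth$congruency_effect_size)))
  list(epochs = eeg_epochs(dat, time, sampling_rate = fs, info = info),
       amplitudes = amp)
}

#' Generate choices and reaction times from planted amplitudes
#'
#' For every trial the decision boundary and non-decision time are
#' computed from the condition's true regression coefficients and the
#' trial's planted absolute component amplitudes; subject-level
#' diffusion parameters are drawn around the condition means. Choice and
#' RT are then sampled from the diffusion simulator under accuracy
#' coding (upper boundary = correct) with an unbiased starting point.
#' RTs are reported in milliseconds from stimulus onset.
#'
#' @param trials Trial table from [generate_session()].
#' @param amplitudes Planted amplitudes from [generate_epochs()],
#'   aligned 1:1 with `trials`.
#' @param truth The [ground_truth()].
#' @param config The [session_config()] (supplies the seed).
#' @param dt Simulator time step in seconds.
#' @return `trials` with added columns `response_correct` (logical) and
#'   `rt_ms`.
#' @export
generate_behaviour <- function(trials, amplitudes, truth, config, dt = 1e-3) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "session_config"))
  if (nrow(amplitudes) != nrow(trials) ||
      !all(amplitudes$subject == trials$subject & amplitudes$trial == trials$trial)) {
    stop("generate_behaviour: amplitudes do not align with trials")
  }
  trials$response_correct <- NA
  trials$rt_ms <- NA_real_
  for (s in unique(trials$subject)) {
    rows <- which(trials$subject == s)
    .local_seed(.substream_seed(config$rng_seed, "behaviour", s), {
      ssd <- truth$true_ddm$subject_sd
      subj <- lapply(c(congruent = "congruent", incongruent = "incongruent"),
                     function(cond) {
        g <- truth$true_ddm[[cond]]
        c(drift = g[["drift"]] + rnorm(1, 0, ssd[["drift"]]),
          boundary = max(0.3, g[["boundary"]] + rnorm(1, 0, ssd[["boundary"]])),
          ndt = max(0.05, g[["ndt"]] + rnorm(1, 0, ssd[["ndt"]])))
      })
      cond <- trials$congruency[rows]
      ae <- abs(amplitudes$amp_early[rows])
      al <- abs(amplitudes$amp_late[rows])
      v <- a <- tau <- numeric(length(rows))
      for (cn in c("congruent", "incongruent")) {
        m <- cond == cn
        co <- truth$true_coefficients[[cn]]
        v[m] <- subj[[cn]][["drift"]]
        a[m] <- subj[[cn]][["boundary"]] +
          co$boundary[["early"]] * ae[m] + co$boundary[["late"]] * al[m]
        tau[m] <- subj[[cn]][["ndt"]] +
          co$ndt[["early"]] * ae[m] + co$ndt[["late"]] * al[m]
      }
      if (any(a <= 0)) {
        stop("generate_behaviour: regression coefficients imply a ",
             "non-positive decision boundary; reject this configuration")
      }
      if (any(tau < 0)) {
        stop("generate_behaviour: regression coefficients imply a ",
             "negative non-decision time; reject this configuration")
      }
      sim <- .ddm_sim_cpp(v, a, tau, 0.5, dt, length(rows))
      trials$response_correct[rows] <- sim$upper
      trials$rt_ms[rows] <- sim$rt * 1000
    })
  }
  trials
}
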