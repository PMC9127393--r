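#' Session configuration for the implicit-association task
#'
#' Describes one recording session of the auditory/visual
#' implicit-association test: block structure, stimulus set, congruency
#' schedule and the epoch geometry of the simulated EEG. Defaults
#' reproduce the study conditions: 20 subjects, 8 blocks (4 congruent, 4
#' incongruent, randomised order), 40 trials per stimulus feature per
#' block (1,280 trials per subject), 128 channels sampled at 200 Hz with
#' epochs from -0.5 to 1.5 s around stimulus onset.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Number of blocks per subject. Must be even when
#'   `congruency_schedule` is `NULL` so that congruent and incongruent
#'   blocks can be balanced.
#' @param trials_per_stimulus_per_block Trials of each stimulus feature
#'   in every block.
#' @param stimulus_features Character vector of stimulus feature labels.
#'   Features containing `"pitch"` are treated as auditory, all others
#'   as visual.
#' @param congruency_schedule Optional character vector (length
#'   `n_blocks`, values `"congruent"`/`"incongruent"`) fixing the block
#'   schedule for every subject. `NULL` (default) randomises a balanced
#'   schedule per subject from the seed.
#' @param sampling_rate EEG sampling rate in Hz.
#' @param epoch_window Numeric `c(start, end)` in seconds relative to
#'   stimulus onset; must straddle 0.
#' @param n_channels Number of EEG channels.
#' @param rng_seed Integer seed governing every random draw derived from
#'   this configuration.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_subjects = 20L,
                           n_blocks = 8L,
                           trials_per_stimulus_per_block = 40L,
                           stimulus_features = c("high_pitch", "low_pitch",
                                                 "small_circle", "large_circle"),
                           congruency_schedule = NULL,
                           sampling_rate = 200,
                           epoch_window = c(-0.5, 1.5),
                           n_channels = 128L,
                           rng_seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_blocks = n_blocks,
              trials_per_stimulus_per_block = trials_per_stimulus_per_block,
              n_channels = n_channels)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("session_config: counts must be positive integers (",
         paste(names(counts)[counts < 1 | counts != round(counts)],
               collapse = ", "), ")")
  }
  if (length(stimulus_features) < 1 || anyDuplicated(stimulus_features)) {
    stop("session_config: stimulus_features must be distinct labels")
  }
  if (!is.null(congruency_schedule)) {
    if (length(congruency_schedule) != n_blocks ||
        !all(congruency_schedule %in% c("congruent", "incongruent"))) {
      stop("session_config: congruency_schedule must assign ",
           "'congruent'/'incongruent' to each of ", n_blocks, " blocks")
    }
  } else if (n_blocks %% 2 != 0) {
    stop("session_config: n_blocks must be even for a balanced randomised ",
         "congruency schedule; supply congruency_schedule explicitly")
  }
  if (length(epoch_window) != 2 || epoch_window[1] >= 0 || epoch_window[2] <= 0) {
    stop("session_config: epoch_window must satisfy start < 0 < end")
  }
  if (sampling_rate <= 0) stop("session_config: sampling_rate must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_blocks = as.integer(n_blocks),
                 trials_per_stimulus_per_block =
                   as.integer(trials_per_stimulus_per_block),
                 stimulus_features = stimulus_features,
                 congruency_schedule = congruency_schedule,
                 sampling_rate = sampling_rate,
                 epoch_window = epoch_window,
                 n_channels = as.integer(n_channels),
                 rng_seed = as.integer(rng_seed)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  per_block <- x$trials_per_stimulus_per_block * length(x$stimulus_features)
  cat("Implicit-association session configuration\n",
      sprintf("  %d subject(s), %d block(s), %d trials/block (%d total/subject)\n",
              x$n_subjects, x$n_blocks, per_block, per_block * x$n_blocks),
      sprintf("  %d channels @ %g Hz, epochs %g..%g s, seed %d\n",
              x$n_channels, x$sampling_rate, x$epoch_window[1],
              x$epoch_window[2], x$rng_seed), sep = "")
  invisible(x)
}

.stimulus_modality <- function(stimulus) {
  ifelse(grepl("pitch", stimulus), "auditory", "visual")
}

#' Generate the trial structure of a session
#'
#' Lays out subjects, blocks, congruency assignments and randomised
#' stimulus orders. Every block contains exactly
#' `trials_per_stimulus_per_block` presentations of each stimulus
#' feature in shuffled order; block congruency follows the schedule (or
#' a per-subject balanced randomisation). Reaction times and choices are
#' added later by [generate_behaviour()].
#'
#' @param config A [session_config()].
#' @return A data frame with columns `subject`, `block`, `trial`
#'   (within subject), `congruency`, `stimulus`, `modality`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  feats <- config$stimulus_features
  per_block <- config$trials_per_stimulus_per_block * length(feats)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    out[[s]] <- .local_seed(
      .substream_seed(config$rng_seed, "session", s), {
        sched <- config$congruency_schedule
        if (is.null(sched)) {
          sched <- sample(rep(c("congruent", "incongruent"),
                              each = config$n_blocks / 2))
        }
        blocks <- lapply(seq_len(config$n_blocks), function(b) {
          stim <- sample(rep(feats, config$trials_per_stimulus_per_block))
          data.frame(subject = s, block = b, congruency = sched[b],
                     stimulus = stim, stringsAsFactors = FALSE)
        })
        do.call(rbind, blocks)
      })
    out[[s]]$trial <- seq_len(nrow(out[[s]]))
  }
  trials <- do.call(rbind, out)
  trials$modality <- .stimulus_modality(trials$stimulus)
  rownames(trials) <- NULL
  trials[, c("subject", "block", "trial", "congruency", "stimulus", "modality")]
}
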