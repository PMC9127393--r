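#' EEG epoch container
#'
#' A lightweight container for stimulus-locked EEG epochs: a
#' trials x channels x samples array in microvolts with a uniform time
#' axis in seconds relative to stimulus onset.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param time Numeric vector of sample times (seconds), strictly
#'   increasing and uniformly spaced, with `length(time) == dim(data)[3]`.
#' @param channels Character vector of channel labels
#'   (`length == dim(data)[2]`).
#' @param sampling_rate Sampling rate in Hz; must match the time axis.
#' @param info Optional named list of provenance metadata (seed, truth
#'   summary, processing history).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, time, channels = NULL, sampling_rate = NULL,
                       info = list()) {
  if (length(dim(data)) != 3) stop("eeg_epochs: data must be a 3-d array")
  if (length(time) != dim(data)[3]) {
    stop("eeg_epochs: time axis length must equal the sample dimension")
  }
  dt <- diff(time)
  if (length(dt)) {
    if (any(dt <= 0) || (length(dt) > 1 && diff(range(dt)) > 1e-6 * mean(dt))) {
      stop("eeg_epochs: time axis must be strictly increasing and uniform")
    }
    if (is.null(sampling_rate)) sampling_rate <- 1 / mean(dt)
    if (abs(1 / mean(dt) - sampling_rate) > 1e-3 * sampling_rate) {
      stop("eeg_epochs: sampling_rate inconsistent with time axis")
    }
  } else if (is.null(sampling_rate)) {
    stop("eeg_epochs: sampling_rate is required for single-sample epochs")
  }
  if (is.null(channels)) channels <- sprintf("ch%03d", seq_len(dim(data)[2]))
  if (length(channels) != dim(data)[2]) {
    stop("eeg_epochs: channel labels must match the channel dimension")
  }
  structure(list(data = data, time = as.numeric(time),
                 channels = as.character(channels),
                 sampling_rate = sampling_rate, info = info),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_epochs: %d trial(s) x %d channel(s) x %d sample(s)\n",
              d[1], d[2], d[3]),
      sprintf("  %g Hz, %.3f..%.3f s relative to stimulus onset\n",
              x$sampling_rate, x$time[1], x$time[length(x$time)]), sep = "")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Subset epochs by trial
#'
#' @param x An [eeg_epochs] object.
#' @param i Trial indices (numeric or logical).
#' @param ... Ignored.
#' @return An [eeg_epochs] object containing the selected trials.
#' @export
`[.eeg_epochs` <- function(x, i, ...) {
  x$data <- x$data[i, , , drop = FALSE]
  x
}

#' Write epochs to a flat binary array with a JSON sidecar
#'
#' The sample data are stored as little-endian doubles in trial-major
#' order (`<stem>.dat`); the sidecar (`<stem>.json`) records dimensions,
#' sampling rate, time origin, channel labels and any metadata in
#' `info`.
#'
#' @param epochs An [eeg_epochs] object.
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  sidecar <- list(dim = dim(epochs$data),
                  sampling_rate = epochs$sampling_rate,
                  t0 = epochs$time[1],
                  channel_labels = epochs$channels,
                  info = epochs$info)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read epochs written by [write_epochs()]
#'
#' @param stem Path without extension.
#' @return An [eeg_epochs] object.
#' @export
read_epochs <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dim)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  time <- side$t0 + seq(0, d[3] - 1) / side$sampling_rate
  eeg_epochs(array(raw, dim = d), time = time,
             channels = side$channel_labels,
             sampling_rate = side$sampling_rate,
             info = if (is.null(side$info)) list() else side$info)
}
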