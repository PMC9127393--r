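#' Zero-phase Butterworth band-pass filtering of epochs
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to
#' every channel of every trial. Zero-phase filtering is used so that
#' component latencies measured downstream by the sliding-window
#' decoder are not shifted by the filter's group delay.
#'
#' @param epochs An [eeg_epochs] object.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Filter order per pass.
#' @return Filtered [eeg_epochs].
#' @export
bandpass_epochs <- function(epochs, low = 0.5, high = 90, order = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  nyq <- epochs$sampling_rate / 2
  if (low <= 0 || high <= low || high >= nyq) {
    stop("bandpass_epochs: band must satisfy 0 < low < high < Nyquist (",
         nyq, " Hz)")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      epochs$data[i, j, ] <- signal::filtfilt(bf, epochs$data[i, j, ])
    }
  }
  epochs$info$bandpass <- c(low = low, high = high, order = order)
  epochs
}

#' Anti-aliased downsampling of epochs
#'
#' Low-pass filters (zero-phase Butterworth, order 8, cutoff at 90% of
#' the target Nyquist) and resamples each channel onto a uniform axis at
#' the target rate spanning the same interval. A 2 s epoch at 512 Hz
#' yields 400 samples at 200 Hz.
#'
#' @param epochs An [eeg_epochs] object.
#' @param target Target sampling rate in Hz (must not exceed the
#'   current rate).
#' @return Downsampled [eeg_epochs].
#' @export
downsample_epochs <- function(epochs, target = 200) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$sampling_rate
  if (target > fs) stop("downsample_epochs: target exceeds sampling rate")
  if (abs(target - fs) < 1e-9) return(epochs)
  d <- dim(epochs$data)
  t_old <- epochs$time
  n_out <- floor((d[3] - 1) * target / fs) + 1
  t_new <- t_old[1] + seq(0, n_out - 1) / target
  bf <- signal::butter(8, 0.9 * (target / 2) / (fs / 2), type = "low")
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      sm <- signal::filtfilt(bf, epochs$data[i, j, ])
      out[i, j, ] <- spline(t_old, sm, xout = t_new)$y
    }
  }
  eeg_epochs(out, t_new, channels = epochs$channels, sampling_rate = target,
             info = c(epochs$info, list(downsampled_from = fs)))
}

#' Reject trials exceeding an absolute amplitude threshold
#'
#' Removes trials whose absolute amplitude exceeds the threshold on any
#' channel or sample. "Exceeds" is strict: a trial peaking at exactly
#' the threshold is kept.
#'
#' @param epochs An [eeg_epochs] object.
#' @param threshold Amplitude bound in microvolts (applied as
#'   +/- threshold).
#' @return List with `epochs` (retained trials) and `rejected` (integer
#'   indices of removed trials).
#' @export
amplitude_reject <- function(epochs, threshold = 120) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (threshold <= 0) stop("amplitude_reject: threshold must be > 0")
  peak <- apply(abs(epochs$data), 1, max)
  rejected <- which(peak > threshold)
  kept <- if (length(rejected)) epochs[-rejected] else epochs
  kept$info$amplitude_threshold <- threshold
  list(epochs = kept, rejected = rejected)
}
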