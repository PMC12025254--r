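#' Construct a raw EEG recording object
#'
#' The container for continuous multi-channel EEG: a channels x samples
#' matrix in microvolts plus channel names, sampling rate and metadata.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param channel_names Character vector, one label per row of `data`.
#' @param sample_rate Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param session Session / class label (e.g. "pre", "post", "T1", "T5").
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names, sample_rate,
                          subject_id = "S01", session = "pre") {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names)) {
    stop("rows(data) must equal length(channel_names)", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  structure(
    list(
      data = data,
      channel_names = as.character(channel_names),
      sample_rate = sample_rate,
      subject_id = as.character(subject_id),
      session = as.character(session)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s, session %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$session, nrow(x$data), ncol(x$data),
    x$sample_rate, ncol(x$data) / x$sample_rate
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# replace the data matrix, keeping metadata
update_data <- function(recording, data) {
  recording$data <- data
  recording
}

#' Band power of each channel of a recording
#'
#' Mean power (signal variance contribution) of the periodogram inside a
#' frequency band. Used by the synthetic-data checks and the myogenic
#' artifact criterion.
#'
#' @param x Numeric vector, matrix (channels x samples) or `eeg_recording`.
#' @param low,high Band edges in Hz.
#' @param sample_rate Sampling rate; taken from the recording if omitted.
#' @return Numeric vector of per-channel band power.
#' @export
band_power <- function(x, low, high, sample_rate = NULL) {
  if (inherits(x, "eeg_recording")) {
    sample_rate <- x$sample_rate
    x <- x$data
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(sample_rate)) stop("sample_rate required", call. = FALSE)
  n <- ncol(x)
  xt <- sweep(t(x), 2, rowMeans(x))
  spec <- Mod(stats::mvfft(xt))^2 / n^2  # sums over all bins to the variance
  freqs <- (seq_len(n) - 1) * sample_rate / n
  folded <- pmin(freqs, sample_rate - freqs)  # count conjugate bins as one band
  keep <- folded >= low & folded <= high
  colSums(spec[keep, , drop = FALSE])
}
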