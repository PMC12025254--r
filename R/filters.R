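# Butterworth band-pass design in zero-pole-gain form, applied as cascaded
# second-order sections. Transfer-function (b, a) realizations of high-order
# band-pass filters are numerically unusable at the low normalized
# frequencies this package needs (e.g. Delta 1-4 Hz at 1000 Hz), so the
# design stays in pole form end to end and each biquad is filtered
# separately with compiled stats::filter passes.

# Analog Butterworth lowpass prototype poles, order n, cutoff 1 rad/s.
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Classic analog prototype -> band-pass transform -> bilinear transform.
#' `order` is the prototype order, so the digital band-pass has `2 * order`
#' poles (the usual "4th-order Butterworth band-pass" convention).
#'
#' @param low,high Band edges in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param order Prototype order (default 4).
#' @return List of class `butter_sos`: `sos` (n_sections x 6 matrix of
#'   b0 b1 b2 a0 a1 a2 rows), plus the design parameters.
#' @export
butter_bandpass <- function(low, high, sample_rate, order = 4) {
  if (!(0 < low && low < high && high < sample_rate / 2)) {
    stop("require 0 < low < high < sample_rate/2", call. = FALSE)
  }
  fs2 <- 2 * sample_rate
  w1 <- fs2 * tan(pi * low / sample_rate)   # pre-warped analog edges
  w2 <- fs2 * tan(pi * high / sample_rate)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  p_proto <- butter_prototype(order)
  # lowpass -> bandpass: each prototype pole maps to a quadratic pair
  b2 <- p_proto * bw / 2
  disc <- sqrt(b2^2 - w0^2)
  p_analog <- c(b2 + disc, b2 - disc)
  # bilinear transform; zeros: 'order' at z=1 and 'order' at z=-1
  p_dig <- (fs2 + p_analog) / (fs2 - p_analog)

  # pair poles into conjugate sections (poles come in conjugate pairs)
  pp <- p_dig[order(-abs(p_dig), Im(p_dig))]
  used <- rep(FALSE, length(pp))
  sections <- vector("list", order)
  s <- 0L
  for (i in seq_along(pp)) {
    if (used[i]) next
    j <- which(!used & abs(pp - Conj(pp[i])) < 1e-8 & seq_along(pp) != i)[1]
    if (is.na(j)) j <- which(!used & seq_along(pp) != i)[1] # real pole fallback
    used[c(i, j)] <- TRUE
    s <- s + 1L
    pr <- c(pp[i], pp[j])
    sections[[s]] <- c(1, -Re(sum(pr)), Re(prod(pr)))
  }
  sos <- matrix(0, nrow = order, ncol = 6)
  for (k in seq_len(order)) {
    sos[k, ] <- c(1, 0, -1, sections[[k]])  # one zero at +1, one at -1 each
  }
  # normalize overall gain to 1 at the geometric band center
  wc <- 2 * pi * sqrt(low * high) / sample_rate
  z <- exp(1i * wc)
  g <- prod(vapply(seq_len(order), function(k) {
    num <- sos[k, 1] + sos[k, 2] / z + sos[k, 3] / z^2
    den <- sos[k, 4] + sos[k, 5] / z + sos[k, 6] / z^2
    Mod(num / den)
  }, numeric(1)))
  sos[, 1:3] <- sos[, 1:3] * (1 / g)^(1 / order)  # spread gain across sections
  structure(
    list(sos = sos, low = low, high = high,
         sample_rate = sample_rate, order = order),
    class = "butter_sos"
  )
}

#' Magnitude response of a second-order-section filter
#'
#' @param filt A `butter_sos` object.
#' @param freqs Frequencies in Hz.
#' @param zero_phase If TRUE, report the squared magnitude of one pass
#'   (the effective response of forward-backward application).
#' @return Numeric vector of magnitude gains.
#' @export
sos_response <- function(filt, freqs, zero_phase = FALSE) {
  z <- exp(1i * 2 * pi * freqs / filt$sample_rate)
  h <- rep(1 + 0i, length(z))
  for (k in seq_len(nrow(filt$sos))) {
    num <- filt$sos[k, 1] + filt$sos[k, 2] / z + filt$sos[k, 3] / z^2
    den <- filt$sos[k, 4] + filt$sos[k, 5] / z + filt$sos[k, 6] / z^2
    h <- h * num / den
  }
  m <- Mod(h)
  if (zero_phase) m^2 else m
}

# One causal pass of a single biquad over a vector (direct form I via two
# compiled stats::filter calls: FIR part then the recursion).
biquad_pass <- function(x, s) {
  v <- stats::filter(x, s[1:3], method = "convolution", sides = 1)
  v[1] <- s[1] * x[1]
  v[2] <- s[1] * x[2] + s[2] * x[1]
  y <- stats::filter(as.numeric(v), -s[5:6], method = "recursive")
  as.numeric(y)
}

sos_forward <- function(x, sos) {
  for (k in seq_len(nrow(sos))) x <- biquad_pass(x, sos[k, ])
  x
}

#' Zero-phase filtering with a second-order-section filter
#'
#' Forward-backward application (no group delay; squared magnitude
#' response). The signal is extended at both ends by odd reflection before
#' filtering to suppress startup transients, with the extension length
#' scaled to the filter's low-frequency time constant.
#'
#' @param filt A `butter_sos` object.
#' @param x Numeric vector or channels x samples matrix.
#' @return Filtered data with the same shape as `x`.
#' @export
sos_filtfilt <- function(filt, x) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- sos_filtfilt(filt, x[i, ])
    return(out)
  }
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * filt$sample_rate / filt$low)))
  if (pad < 1L) stop("signal too short to filter", call. = FALSE)
  head_ext <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(head_ext, x, tail_ext)
  y <- sos_forward(ext, filt$sos)
  y <- rev(sos_forward(rev(y), filt$sos))
  y[seq(pad + 1, pad + n)]
}

#' Band-pass filter a recording (zero-phase Butterworth)
#'
#' The broadband cleanup stage: removes low-frequency drift below `low` and
#' high-frequency noise above `high` with a zero-phase 4th-order Butterworth
#' band-pass (forward-backward application doubles the effective magnitude
#' order).
#'
#' @param recording An `eeg_recording`.
#' @param low,high Cutoffs in Hz (defaults 0.5 and 50).
#' @param order Butterworth prototype order (default 4).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(recording, low = 0.5, high = 50, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  filt <- butter_bandpass(low, high, recording$sample_rate, order)
  update_data(recording, sos_filtfilt(filt, recording$data))
}

#' Decompose a recording into frequency-band copies
#'
#' One zero-phase Butterworth band-pass per requested band.
#'
#' @param recording An `eeg_recording` (typically already broadband
#'   filtered).
#' @param bands A data.frame with columns `name`, `low`, `high`; defaults to
#'   the canonical seven-band table of [eeg_bands()].
#' @param order Butterworth prototype order (default 4).
#' @return Named list mapping band name to filtered `eeg_recording`.
#' @export
split_bands <- function(recording, bands = eeg_bands(), order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(bands) == 0) return(structure(list(), names = character(0)))
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    out[[i]] <- bandpass_filter(recording, bands$low[i], bands$high[i], order)
  }
  out
}
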