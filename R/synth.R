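#' Configuration for the synthetic EEG generator
#'
#' The generator emulates resting multi-channel EEG as a sum of per-band
#' narrowband oscillations (band-pass-filtered Gaussian noise mixed across
#' channels through a fixed random spatial mixing matrix), 1/f^alpha
#' background noise, and optional ocular/myogenic artifacts. A binary class
#' effect ("pre" vs "post") is expressed as a multiplicative power ratio in
#' one band, mirroring how band power is analyzed in EEG.
#'
#' @param n_subjects Number of subjects (each contributes one "pre" and one
#'   "post" recording).
#' @param n_channels Number of channels (16: the packaged montage).
#' @param sample_rate Sampling rate, Hz. With the model's 2 s / 2000-sample
#'   segments this is 1000 Hz.
#' @param duration_s Seconds per recording; must cover one analysis window.
#' @param effect_band Band carrying the class effect (one of the seven
#'   canonical band names).
#' @param effect_ratio Oscillation power ratio post/pre in `effect_band`
#'   (>= 0; 1 makes the class generators distributionally identical).
#' @param background_exponent Spectral slope alpha of the 1/f^alpha
#'   background.
#' @param background_amplitude Background noise standard deviation, uV.
#' @param oscillation_amplitudes Named numeric vector of per-band
#'   oscillation standard deviations, uV (names must be the band names).
#' @param artifact_rate Artifact events per minute (0 disables).
#' @param tone_hz,tone_amplitude Optional deterministic sinusoid added to
#'   every channel (validation aid for spectral checks); `NULL` disables.
#' @param seed Integer RNG seed; all generation is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 17,
                         n_channels = 16,
                         sample_rate = 1000,
                         duration_s = 11,
                         effect_band = "Gamma",
                         effect_ratio = 2,
                         background_exponent = 1,
                         background_amplitude = 5,
                         oscillation_amplitudes = c(
                           Delta = 4, Theta = 3, Alpha1 = 3, Alpha2 = 2.5,
                           Beta1 = 2, Beta2 = 1.5, Gamma = 1.5
                         ),
                         artifact_rate = 0,
                         tone_hz = NULL,
                         tone_amplitude = NULL,
                         seed = 1L) {
  bands <- eeg_bands()
  if (!effect_band %in% bands$name) {
    stop("unknown effect_band '", effect_band, "'; valid bands: ",
         paste(bands$name, collapse = ", "), call. = FALSE)
  }
  if (effect_ratio < 0) stop("effect_ratio must be >= 0", call. = FALSE)
  if (any(oscillation_amplitudes < 0) || background_amplitude < 0) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (!all(names(oscillation_amplitudes) %in% bands$name)) {
    stop("oscillation_amplitudes names must be canonical band names",
         call. = FALSE)
  }
  if (duration_s < 2) {
    stop("duration_s must cover at least one 2 s analysis window",
         call. = FALSE)
  }
  structure(
    list(
      n_subjects = n_subjects, n_channels = n_channels,
      sample_rate = sample_rate, duration_s = duration_s,
      effect_band = effect_band, effect_ratio = effect_ratio,
      background_exponent = background_exponent,
      background_amplitude = background_amplitude,
      oscillation_amplitudes = oscillation_amplitudes,
      artifact_rate = artifact_rate,
      tone_hz = tone_hz, tone_amplitude = tone_amplitude,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# 1/f^alpha noise via spectral shaping, unit variance.
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  f <- c(1, seq_len(n - 1))            # avoid DC blowup
  f <- pmin(f, n - f + 1)              # fold to two-sided spectrum
  shaped <- Re(stats::fft(stats::fft(w) * f^(-alpha / 2), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

# narrowband unit-variance source: band-passed white noise
narrowband_source <- function(n, low, high, sample_rate) {
  filt <- butter_bandpass(low, high, sample_rate, order = 4)
  s <- sos_filtfilt(filt, stats::rnorm(n))
  s / stats::sd(s)
}

#' Generate one synthetic EEG recording
#'
#' See [synth_config()] for the generative model. Each band is driven by
#' four independent narrowband sources mixed into the channels through a
#' random spatial mixing matrix (rows normalized so every channel carries
#' the band's configured standard deviation); for `class_label = "post"`
#' the source variance in the effect band is multiplied by
#' `effect_ratio`. Fully reproducible from `(seed, subject_id,
#' class_label)`.
#'
#' @param config A `synth_config`.
#' @param subject_id Subject identifier (enters the RNG stream).
#' @param class_label `"pre"` or `"post"`.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(config, subject_id = "S01",
                               class_label = c("pre", "post")) {
  stopifnot(inherits(config, "synth_config"))
  class_label <- match.arg(class_label)
  n <- round(config$duration_s * config$sample_rate)
  nc <- config$n_channels
  labels <- eeg_montage()$label[seq_len(nc)]
  bands <- eeg_bands()
  n_src <- 4L

  # spatial mixing is a per-(seed, subject) property, shared by both classes
  mix_seed <- derive_seed(config$seed, paste0("mix:", subject_id))
  mixing <- with_seed(mix_seed, {
    lapply(seq_len(nrow(bands)), function(i) {
      m <- matrix(stats::runif(nc * n_src, 0.2, 1), nc, n_src)
      m / sqrt(rowSums(m^2))
    })
  })

  sig_seed <- derive_seed(config$seed,
                          paste0("rec:", subject_id, ":", class_label))
  data <- with_seed(sig_seed, {
    x <- matrix(0, nc, n)
    for (i in seq_len(nrow(bands))) {
      amp <- config$oscillation_amplitudes[bands$name[i]]
      if (is.na(amp)) amp <- 0
      if (amp > 0) {
        src <- vapply(seq_len(n_src), function(j) {
          narrowband_source(n, bands$low[i], bands$high[i], config$sample_rate)
        }, numeric(n))
        x <- x + amp * mixing[[i]] %*% t(src)
      }
    }
    if (config$background_amplitude > 0) {
      for (ch in seq_len(nc)) {
        x[ch, ] <- x[ch, ] + config$background_amplitude *
          pink_noise(n, config$background_exponent)
      }
    }
    # class effect: rescale everything inside the effect band so that the
    # measured post/pre band-power ratio equals effect_ratio
    if (class_label == "post" && config$effect_ratio != 1) {
      bd <- band_definition(config$effect_band)
      filt <- butter_bandpass(bd$low, bd$high, config$sample_rate, 4)
      x <- x + (sqrt(config$effect_ratio) - 1) * sos_filtfilt(filt, x)
    }
    x
  })

  if (!is.null(config$tone_hz) && !is.null(config$tone_amplitude) &&
      config$tone_amplitude > 0) {
    tt <- seq_len(n) / config$sample_rate
    data <- data + matrix(
      rep(config$tone_amplitude * sin(2 * pi * config$tone_hz * tt), each = nc),
      nc, n
    )
  }

  rec <- eeg_recording(data, labels, config$sample_rate,
                       subject_id = subject_id, session = class_label)

  if (config$artifact_rate > 0) {
    art_seed <- derive_seed(config$seed,
                            paste0("art:", subject_id, ":", class_label))
    rec <- inject_artifacts(rec, kind = "ocular", seed = art_seed,
                            rate = config$artifact_rate)$recording
  }
  rec
}

#' Generate a labeled synthetic dataset
#'
#' One "pre" and one "post" recording per subject (a paired
#' pre/post-training design).
#'
#' @param config A `synth_config`.
#' @return List with `recordings` (list of `eeg_recording`) and `manifest`
#'   (data.frame: subject_id, session, class with pre = 0, post = 1).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  recs <- list()
  manifest <- data.frame(subject_id = character(0), session = character(0),
                         class = integer(0), stringsAsFactors = FALSE)
  for (id in ids) {
    for (lab in c("pre", "post")) {
      recs[[paste(id, lab, sep = "_")]] <- generate_recording(config, id, lab)
      manifest <- rbind(manifest, data.frame(
        subject_id = id, session = lab,
        class = if (lab == "post") 1L else 0L, stringsAsFactors = FALSE
      ))
    }
  }
  list(recordings = recs, manifest = manifest)
}

# frontally-weighted (ocular) and temporally-weighted (myogenic) channel
# projection weights for the 16-label montage
artifact_topography <- function(kind, channel_names) {
  w_oc <- c(Fp1 = 1, Fp2 = 1, F7 = 0.55, F8 = 0.55, F3 = 0.5, F4 = 0.5,
            Fz = 0.45, FCz = 0.35, C3 = 0.2, C4 = 0.2, Cz = 0.15,
            P7 = 0.05, P8 = 0.05, Pz = 0.05, O1 = 0.03, O2 = 0.03)
  w_my <- c(Fp1 = 0.2, Fp2 = 0.2, F7 = 1, F8 = 0.95, F3 = 0.3, F4 = 0.3,
            Fz = 0.1, FCz = 0.1, C3 = 0.2, C4 = 0.2, Cz = 0.05,
            P7 = 0.9, P8 = 0.85, Pz = 0.1, O1 = 0.15, O2 = 0.15)
  w <- if (kind == "ocular") w_oc else w_my
  unname(w[channel_names])
}

#' Inject artifacts into a recording, returning ground truth
#'
#' Ocular artifacts are slow (< 4 Hz) blink-like transients projected with
#' frontal weighting (strongest on Fp1/Fp2); myogenic artifacts are
#' high-frequency (> 30 Hz) bursts with temporal-region weighting. The
#' clean input and the reference trace are returned so downstream removal
#' can be scored against ground truth.
#'
#' @param recording An `eeg_recording`.
#' @param kind `"ocular"` or `"myogenic"`.
#' @param seed Integer seed.
#' @param rate Events per minute.
#' @param amplitude Peak artifact amplitude, uV (0 returns the input
#'   unchanged).
#' @return List: `recording` (contaminated), `reference` (the single-channel
#'   artifact source trace), `clean` (the original recording),
#'   `component` (channels x samples matrix actually added).
#' @export
inject_artifacts <- function(recording, kind = c("ocular", "myogenic"),
                             seed = 1L, rate = 6, amplitude = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  kind <- match.arg(kind)
  if (is.null(amplitude)) amplitude <- if (kind == "ocular") 150 else 100
  n <- ncol(recording$data)
  fs <- recording$sample_rate
  if (amplitude == 0 || rate <= 0) {
    return(list(recording = recording, reference = numeric(n),
                clean = recording, component = matrix(0, nrow(recording$data), n)))
  }
  trace <- with_seed(derive_seed(seed, paste0("inject:", kind)), {
    n_events <- max(1L, stats::rpois(1, rate * n / fs / 60))
    centers <- sort(stats::runif(n_events, 0.05, 0.95)) * n
    tr <- numeric(n)
    if (kind == "ocular") {
      half <- round(0.15 * fs)            # ~300 ms blink
      shape <- cos(seq(-pi / 2, pi / 2, length.out = 2 * half + 1))^2
      for (c0 in centers) {
        idx <- round(c0) + seq(-half, half)
        ok <- idx >= 1 & idx <= n
        tr[idx[ok]] <- tr[idx[ok]] + shape[ok] * stats::runif(1, 0.7, 1)
      }
    } else {
      filt <- butter_bandpass(32, min(95, fs / 2 - 5), fs, 4)
      burst_len <- round(0.5 * fs)
      for (c0 in centers) {
        idx <- round(c0) + seq_len(burst_len) - round(burst_len / 2)
        ok <- idx >= 1 & idx <= n
        burst <- sos_filtfilt(filt, stats::rnorm(burst_len))
        env <- sin(seq(0, pi, length.out = burst_len))^2
        tr[idx[ok]] <- tr[idx[ok]] + (burst * env)[ok] * stats::runif(1, 0.7, 1)
      }
      if (stats::sd(tr) > 0) tr <- tr / max(abs(tr))
    }
    tr
  })
  w <- artifact_topography(kind, recording$channel_names)
  component <- amplitude * outer(w, trace)
  out <- update_data(recording, recording$data + component)
  list(recording = out, reference = amplitude * trace, clean = recording,
       component = component)
}
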