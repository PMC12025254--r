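#' Construct a segment set
#'
#' Container for model-ready epochs: an n x channels x window tensor with
#' binary labels and subject identifiers.
#'
#' @param segments Numeric array n x channels x window_samples.
#' @param labels Integer vector in \{0, 1\}, length n.
#' @param subject_ids Character vector, length n.
#' @param band Band name the segments were filtered to (or "broadband").
#' @param sample_rate Sampling rate in Hz.
#' @return Object of class `segment_set`.
#' @export
segment_set <- function(segments, labels, subject_ids, band = "broadband",
                        sample_rate = 1000) {
  stopifnot(length(dim(segments)) == 3)
  n <- dim(segments)[1]
  stopifnot(length(labels) == n, length(subject_ids) == n,
            all(labels %in% c(0L, 1L)))
  structure(
    list(segments = segments, labels = as.integer(labels),
         subject_ids = as.character(subject_ids), band = band,
         sample_rate = sample_rate),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<segment_set> band %s: %d segments of %d channels x %d samples (classes: %d/%d)\n",
    x$band, d[1], d[2], d[3], sum(x$labels == 0), sum(x$labels == 1)
  ))
  invisible(x)
}

#' Number of sliding-window segments
#'
#' `floor((T - W) / S) + 1` for a signal of `T` samples, window `W` and
#' step `S` (0 when `T < W`).
#'
#' @param n_samples,window_samples,step_samples Sizes in samples.
#' @return Integer segment count.
#' @export
n_segments <- function(n_samples, window_samples, step_samples) {
  if (n_samples < window_samples) return(0L)
  as.integer(floor((n_samples - window_samples) / step_samples) + 1)
}

#' Slice a recording into overlapping fixed-length epochs
#'
#' Sliding-window segmentation (default 2 s window, 1 s step, i.e. 50%
#' overlap at the defaults), propagating the recording's label and subject
#' to every segment. Session labels "post" and "T5" map to class 1,
#' everything else to class 0.
#'
#' @param recording An `eeg_recording`.
#' @param window_s Window length, seconds (default 2).
#' @param step_s Step size, seconds (default 1).
#' @return A `segment_set`; empty (with a warning) when the recording is
#'   shorter than one window.
#' @export
segment_recording <- function(recording, window_s = 2, step_s = 1) {
  stopifnot(inherits(recording, "eeg_recording"),
            window_s > 0, step_s > 0)
  fs <- recording$sample_rate
  w <- round(window_s * fs)
  s <- round(step_s * fs)
  n <- ncol(recording$data)
  nc <- nrow(recording$data)
  k <- n_segments(n, w, s)
  label <- if (recording$session %in% c("post", "T5")) 1L else 0L
  if (k == 0) {
    warning("recording shorter than one window; returning empty segment set")
    return(segment_set(array(0, c(0, nc, w)), integer(0), character(0),
                       sample_rate = fs))
  }
  segs <- array(0, c(k, nc, w))
  for (i in seq_len(k)) {
    start <- (i - 1) * s + 1
    segs[i, , ] <- recording$data[, start:(start + w - 1)]
  }
  segment_set(segs, rep(label, k), rep(recording$subject_id, k),
              sample_rate = fs)
}

# concatenate segment sets (same band/shape)
bind_segment_sets <- function(sets) {
  sets <- Filter(function(s) dim(s$segments)[1] > 0, sets)
  if (!length(sets)) stop("no non-empty segment sets", call. = FALSE)
  d <- dim(sets[[1]]$segments)
  total <- sum(vapply(sets, function(s) dim(s$segments)[1], integer(1)))
  segs <- array(0, c(total, d[2], d[3]))
  labels <- integer(0); ids <- character(0)
  at <- 0L
  for (s in sets) {
    k <- dim(s$segments)[1]
    segs[at + seq_len(k), , ] <- s$segments
    labels <- c(labels, s$labels)
    ids <- c(ids, s$subject_ids)
    at <- at + k
  }
  segment_set(segs, labels, ids, band = sets[[1]]$band,
              sample_rate = sets[[1]]$sample_rate)
}

#' Run the full preprocessing pipeline on one recording
#'
#' Stage order: broadband band-pass filter, ocular artifact removal (when a
#' reference trace is supplied), myogenic artifact suppression, bad-channel
#' interpolation, band decomposition, sliding-window segmentation. Each
#' stage can be toggled; a provenance log of every stage's parameters is
#' returned alongside the per-band segment sets.
#'
#' @param recording An `eeg_recording`.
#' @param bands Band table (subset of [eeg_bands()]); defaults to all seven.
#' @param low,high Broadband filter cutoffs, Hz.
#' @param reference_trace Optional EOG-like reference for ocular removal
#'   (NULL skips the stage).
#' @param r_threshold Ocular component correlation threshold.
#' @param suppress_myogenic Run the myogenic ICA stage?
#' @param hf_threshold Myogenic high-frequency power-fraction threshold.
#' @param bad_channels Channel labels to reconstruct (empty skips).
#' @param window_s,step_s Segmentation parameters, seconds.
#' @param seed Seed for the ICA stages.
#' @return List: `bands` (named list of `segment_set`), `provenance`
#'   (data.frame logging each stage and its parameters), `reports` (ICA
#'   stage reports).
#' @export
preprocess_pipeline <- function(recording,
                                bands = eeg_bands(),
                                low = 0.5, high = 50,
                                reference_trace = NULL,
                                r_threshold = 0.8,
                                suppress_myogenic = FALSE,
                                hf_threshold = 0.6,
                                bad_channels = character(0),
                                window_s = 2, step_s = 1,
                                seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  prov <- list()
  log_stage <- function(stage, params) {
    prov[[length(prov) + 1]] <<- data.frame(
      stage = stage, parameters = params, stringsAsFactors = FALSE
    )
  }
  reports <- list()

  rec <- bandpass_filter(recording, low, high)
  log_stage("bandpass_filter", sprintf("low=%g high=%g order=4 zero_phase", low, high))

  if (!is.null(reference_trace)) {
    res <- remove_ocular_artifacts(rec, reference_trace, r_threshold,
                                   seed = derive_seed(seed, "ocular"))
    rec <- res$recording
    reports$ocular <- res$report
    log_stage("remove_ocular_artifacts",
              sprintf("r_threshold=%g removed=%d status=%s", r_threshold,
                      sum(res$report$removed), res$status))
  }
  if (isTRUE(suppress_myogenic)) {
    res <- suppress_myogenic_artifacts(rec, hf_threshold,
                                       seed = derive_seed(seed, "myogenic"))
    rec <- res$recording
    reports$myogenic <- res$report
    log_stage("suppress_myogenic_artifacts",
              sprintf("hf_threshold=%g removed=%d status=%s", hf_threshold,
                      sum(res$report$removed), res$status))
  }
  if (length(bad_channels)) {
    rec <- interpolate_bad_channels(rec, bad_channels)
    log_stage("interpolate_bad_channels", paste(bad_channels, collapse = ","))
  }

  band_recs <- split_bands(rec, bands)
  log_stage("split_bands", paste(bands$name, collapse = ","))

  out <- lapply(band_recs, function(br) {
    ss <- segment_recording(br, window_s, step_s)
    ss$band <- br$session  # placeholder, fixed below
    ss
  })
  for (nm in names(out)) out[[nm]]$band <- nm
  log_stage("segment", sprintf("window_s=%g step_s=%g", window_s, step_s))

  list(
    bands = out,
    provenance = do.call(rbind, prov),
    reports = reports
  )
}

#' Preprocess a whole dataset into per-band segment sets
#'
#' Applies [preprocess_pipeline()] to every recording of a dataset (as
#' produced by [generate_dataset()] or read from EDF files plus a label
#' manifest) and pools the segments per band.
#'
#' @param dataset List with `recordings` and `manifest` (see
#'   [generate_dataset()]).
#' @param ... Passed to [preprocess_pipeline()].
#' @return Named list mapping band name to pooled `segment_set`.
#' @export
preprocess_dataset <- function(dataset, ...) {
  per_rec <- lapply(dataset$recordings, function(r) {
    preprocess_pipeline(r, ...)$bands
  })
  band_names <- names(per_rec[[1]])
  out <- lapply(band_names, function(b) {
    bind_segment_sets(lapply(per_rec, `[[`, b))
  })
  names(out) <- band_names
  out
}
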