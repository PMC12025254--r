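# Legendre polynomial values P_1..P_nmax at x (vectorized via recurrence)
legendre_terms <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1] <- p
  if (nmax > 1) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      pm1 <- p
      p <- pn
      out[, n] <- pn
    }
  }
  out
}

# Perrin-style spherical spline kernel g(cos theta), order m, nterms terms;
# preserves the shape of its input
spline_g <- function(cosang, m = 4, nterms = 7) {
  n <- seq_len(nterms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  g <- as.numeric(legendre_terms(as.numeric(cosang), nterms) %*% coef) / (4 * pi)
  if (!is.null(dim(cosang))) dim(g) <- dim(cosang)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  g
}

#' Reconstruct bad channels by spherical spline interpolation
#'
#' Perrin-style spherical splines (order m = 4, 7 Legendre terms) on the
#' idealized unit-sphere montage of [eeg_montage()]: the spline is fitted to
#' the good channels at every time point (one linear solve for all time
#' points) and evaluated at the bad-channel positions. Good channels are
#' returned unchanged.
#'
#' @param recording An `eeg_recording` using montage channel labels.
#' @param bad_channels Character vector of labels to reconstruct (empty
#'   vector returns the input unchanged).
#' @param m Spline order (default 4).
#' @param nterms Number of Legendre terms (default 7).
#' @return The `eeg_recording` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(recording, bad_channels,
                                     m = 4, nterms = 7) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(bad_channels) == 0) return(recording)
  bad_channels <- canonical_channels(bad_channels)
  chan <- canonical_channels(recording$channel_names)
  bad_idx <- match(bad_channels, chan)
  if (anyNA(bad_idx)) stop("bad_channels must be channels of the recording",
                           call. = FALSE)
  good_idx <- setdiff(seq_along(chan), bad_idx)
  if (length(good_idx) < 4) {
    stop("at least 4 good channels are required", call. = FALSE)
  }
  mont <- eeg_montage()
  pos <- as.matrix(mont[match(chan, mont$label), c("x", "y", "z")])
  gpos <- pos[good_idx, , drop = FALSE]
  bpos <- pos[bad_idx, , drop = FALSE]

  gg <- spline_g(pmin(pmax(tcrossprod(gpos), -1), 1), m, nterms)
  gb <- spline_g(pmin(pmax(bpos %*% t(gpos), -1), 1), m, nterms)

  ng <- length(good_idx)
  lhs <- rbind(cbind(gg + diag(1e-8, ng), 1), c(rep(1, ng), 0))
  rhs <- rbind(recording$data[good_idx, , drop = FALSE], 0)
  sol <- solve(lhs, rhs)
  est <- gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(gb), ncol(recording$data), byrow = TRUE)

  data <- recording$data
  data[bad_idx, ] <- est
  update_data(recording, data)
}
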