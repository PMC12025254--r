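#' Monte-Carlo predictive uncertainty
#'
#' Runs `K` stochastic forward passes (fresh reparameterization noise each
#' pass), averages the class probabilities, and scores each sample's
#' uncertainty as the normalized Shannon entropy of the mean probability
#' vector: `H(p_bar) / log(n_classes)`, which lies in [0, 1] (0 for a
#' degenerate prediction, 1 for a uniform one). Deterministic under a
#' fixed seed.
#'
#' @param model A trained `duformer_model` (with the reparameterization
#'   head; models without it yield identical passes and entropy of the
#'   deterministic probabilities).
#' @param x A `segment_set` or array (n, channels, samples).
#' @param K Number of Monte-Carlo draws (default 30).
#' @param seed Integer seed.
#' @return An `uncertainty_report`: data.frame `samples` (predicted_class,
#'   mean class probabilities, uncertainty, sd of the class-1 probability
#'   across draws) plus fields `K`, `seed`, `band`.
#' @export
mc_predict <- function(model, x, K = 30, seed = 1L) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  band <- if (inherits(x, "segment_set")) x$band else "unknown"
  if (inherits(x, "segment_set")) x <- x$segments
  n <- dim(x)[1]
  nc <- model$config$n_classes
  acc <- matrix(0, n, nc)
  p1_draws <- matrix(0, n, K)
  pc <- prediction_precompute(model, x)  # reused across the K passes
  set.seed(derive_seed(seed, "mc"))
  for (k in seq_len(K)) {
    p <- predict_proba(model, x, mode = "mc", precomp = pc)
    acc <- acc + p
    p1_draws[, k] <- p[, 2]
  }
  p_bar <- acc / K
  h <- -rowSums(ifelse(p_bar > 0, p_bar * log(p_bar), 0))
  uncertainty <- h / log(nc)
  samples <- data.frame(
    predicted_class = max.col(p_bar) - 1L,
    uncertainty = uncertainty,
    p_sd = apply(p1_draws, 1, stats::sd)
  )
  for (j in seq_len(nc)) samples[[paste0("p", j - 1)]] <- p_bar[, j]
  structure(list(samples = samples, K = K, seed = as.integer(seed),
                 band = band),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> band %s: %d samples, K = %d draws\n",
              x$band, nrow(x$samples), x$K))
  print(summary(x$samples$uncertainty))
  invisible(x)
}

#' Occurrence-rate histogram of prediction uncertainty
#'
#' Fraction of samples per uncertainty bin ("Uncertainty Level" vs
#' "Occurrence Rate"); rates sum to 1.
#'
#' @param report An `uncertainty_report` (or numeric vector of
#'   uncertainties).
#' @param bin_edges Increasing edges covering [0, 1] (default width 0.1).
#' @return List: `bin_edges`, `rates` (length `length(bin_edges) - 1`).
#' @export
uncertainty_histogram <- function(report, bin_edges = seq(0, 1, by = 0.1)) {
  u <- if (inherits(report, "uncertainty_report")) {
    report$samples$uncertainty
  } else {
    report
  }
  if (length(u) == 0) stop("empty uncertainty report", call. = FALSE)
  counts <- graphics::hist(u, breaks = bin_edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  list(bin_edges = bin_edges, rates = counts / length(u))
}

#' Fraction of predictions below an uncertainty threshold
#'
#' The "acceptable classification" rate: the fraction of samples whose
#' uncertainty does not exceed the threshold (default 0.3).
#'
#' @param report An `uncertainty_report` (or numeric vector).
#' @param threshold Acceptance threshold in [0, 1].
#' @return Fraction in [0, 1].
#' @export
acceptance_rate <- function(report, threshold = 0.3) {
  u <- if (inherits(report, "uncertainty_report")) {
    report$samples$uncertainty
  } else {
    report
  }
  mean(u <= threshold)
}

#' Plot the uncertainty occurrence-rate histogram
#'
#' @param x An `uncertainty_report`.
#' @param bin_edges Histogram bin edges.
#' @param ... Further arguments to [graphics::barplot()].
#' @export
plot.uncertainty_report <- function(x, bin_edges = seq(0, 1, by = 0.1),
                                    ...) {
  hh <- uncertainty_histogram(x, bin_edges)
  mids <- utils::head(bin_edges, -1) + diff(bin_edges) / 2
  graphics::barplot(hh$rates, names.arg = sprintf("%.1f", mids),
                    xlab = "Uncertainty Level", ylab = "Occurrence Rate",
                    ...)
  invisible(x)
}
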