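# Independent oracles used across the test files. These deliberately use
# naive, explicit computations (loops, full enumeration) so they share no
# code path with the implementation they check.

# Brute-force separable attention: explicit per-(batch, head) softmax over
# tokens, explicit weighted sum for the context vector, explicit gating.
brute_force_smhsa <- function(x, w_i, w_k, w_v, w_out, b_out, n_heads,
                              gate = "relu") {
  d <- dim(x)  # (B, T, E)
  e <- d[3]
  dh <- e / n_heads
  out <- array(0, d)
  for (b in seq_len(d[1])) {
    xb <- matrix(x[b, , ], d[2], e)
    yb <- matrix(0, d[2], e)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      i_scores <- as.numeric(xb %*% w_i[, h])
      a <- exp(i_scores - max(i_scores))
      a <- a / sum(a)
      kb <- xb %*% w_k[, cols, drop = FALSE]
      vb <- xb %*% w_v[, cols, drop = FALSE]
      ctx <- numeric(dh)
      for (t in seq_len(d[2])) ctx <- ctx + a[t] * kb[t, ]
      gv <- if (gate == "sigmoid") 1 / (1 + exp(-vb)) else pmax(vb, 0)
      for (t in seq_len(d[2])) yb[t, cols] <- gv[t, ] * ctx
    }
    out[b, , ] <- yb %*% w_out +
      matrix(b_out, d[2], e, byrow = TRUE)
  }
  out
}

# Exhaustive Mann-Whitney two-sided p: enumerate every assignment of the
# pooled values to the x-group, count assignments with U as or more extreme
# (two-sided via doubling the smaller tail).
brute_force_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, u_stat)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# random eeg_recording with given channel count (pure noise, montage labels)
random_recording <- function(n_channels = 16, n_samples = 4000, fs = 1000,
                             seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_channels * n_samples), n_channels),
                eeg_montage()$label[seq_len(n_channels)], fs)
}

# small model config used throughout the unit tests
tiny_config <- function(...) {
  duformer_config(n_channels = 4, n_samples = 50, n_filters = 4,
                  temporal_kernel = 7, stride_large = 6, stride_small = 2,
                  embed_dim = 4, n_heads = 2, ffn_expansion = 2, ...)
}

# amplitude of a sinusoid in a signal, by least squares on the central part
tone_amplitude <- function(x, freq, fs) {
  n <- length(x)
  idx <- seq(round(n * 0.25), round(n * 0.75))
  tt <- idx / fs
  fit <- lm(x[idx] ~ sin(2 * pi * freq * tt) + cos(2 * pi * freq * tt))
  sqrt(sum(coef(fit)[2:3]^2))
}

subset_segments_for_test <- function(segs, idx) {
  duformer:::subset_segments(segs, idx)
}

# deterministic forward pass exposing the Gaussian embedding of a fit
predict_embedding_for_test <- function(model, segs) {
  x <- segs$segments / model$input_scale
  duformer:::duformer_forward(model$params, model$buffers, x, model$config,
                              "deterministic")
}
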