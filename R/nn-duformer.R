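#' Model configuration for DU-former
#'
#' All architecture hyperparameters plus the two ablation switches. The
#' canonical settings are the defaults: a 1 x 25 temporal kernel, a
#' 16 x 1 spatial kernel collapsing the electrode axis, two Transformer
#' encoder blocks with separable multi-head self-attention, and a Gaussian
#' reparameterization head.
#'
#' @param n_channels Input channels (16).
#' @param n_samples Samples per segment (2000 = 2 s at 1000 Hz).
#' @param n_filters Convolution output channels F (default 32).
#' @param temporal_kernel Temporal kernel length (default 25).
#' @param stride_large Temporal stride of the large-kernel branch; sets the
#'   token count (default 5).
#' @param stride_small Temporal stride of the small-kernel branch before
#'   its max-pooling stage (default 1; the pool is solved adaptively so the
#'   token counts match).
#' @param embed_dim Token embedding size E (default = `n_filters`; must be
#'   divisible by `n_heads`).
#' @param n_heads Attention heads (default 4).
#' @param ffn_expansion Feed-forward hidden expansion ratio (default 4).
#' @param n_blocks Encoder blocks (default 2).
#' @param n_classes Output classes (default 2).
#' @param dropout Dropout fraction on the attention/FFN sublayer outputs
#'   during training (default 0).
#' @param kl_weight Weight lambda of the KL regularizer on the Gaussian
#'   embedding (default 1e-4; 0 recovers pure cross-entropy).
#' @param sigma_floor Lower bound added to the softplus standard deviation
#'   (default 1e-4).
#' @param conv_kernel_tokens Token-axis kernel width of the mean branch's
#'   convolution in the reparameterization head (default 3).
#' @param attention_gate `"relu"` (default, the separable-attention
#'   convention) or `"sigmoid"` gating of V.
#' @param fusion `"sum"` (default) or `"concat"` (concatenation followed by
#'   a linear projection back to `embed_dim`).
#' @param use_smhsa Ablation switch: FALSE removes the attention sublayer
#'   (residual FFN blocks remain).
#' @param use_reparam Ablation switch: FALSE feeds the pooled deterministic
#'   encoder feature straight to the classifier.
#' @param seed Seed for weight initialization.
#' @return A `duformer_config` list.
#' @export
duformer_config <- function(n_channels = 16, n_samples = 2000,
                            n_filters = 32, temporal_kernel = 25,
                            stride_large = 5, stride_small = 1,
                            embed_dim = n_filters, n_heads = 4,
                            ffn_expansion = 4, n_blocks = 2, n_classes = 2,
                            dropout = 0, kl_weight = 1e-4,
                            sigma_floor = 1e-4, conv_kernel_tokens = 3,
                            attention_gate = c("relu", "sigmoid"),
                            fusion = c("sum", "concat"),
                            use_smhsa = TRUE, use_reparam = TRUE,
                            seed = 1L) {
  attention_gate <- match.arg(attention_gate)
  fusion <- match.arg(fusion)
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  t_large <- floor((n_samples - temporal_kernel) / stride_large) + 1
  t_small <- floor((n_samples - temporal_kernel) / stride_small) + 1
  if (t_small < t_large) {
    stop("stride_small must not produce fewer tokens than stride_large",
         call. = FALSE)
  }
  structure(
    list(n_channels = n_channels, n_samples = n_samples,
         n_filters = n_filters, temporal_kernel = temporal_kernel,
         stride_large = stride_large, stride_small = stride_small,
         embed_dim = embed_dim, n_heads = n_heads,
         ffn_expansion = ffn_expansion, n_blocks = n_blocks,
         n_classes = n_classes, dropout = dropout, kl_weight = kl_weight,
         sigma_floor = sigma_floor, conv_kernel_tokens = conv_kernel_tokens,
         attention_gate = attention_gate, fusion = fusion,
         use_smhsa = use_smhsa, use_reparam = use_reparam,
         n_tokens = t_large, n_tokens_small = t_small,
         seed = as.integer(seed)),
    class = "duformer_config"
  )
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

duformer_init <- function(config) {
  with_seed(derive_seed(config$seed, "init"), {
    f <- config$n_filters; k <- config$temporal_kernel
    c_ <- config$n_channels; e <- config$embed_dim
    hid <- e * config$ffn_expansion
    p <- list()
    for (br in c("cl", "cs")) {
      p[[paste0(br, "_wt")]] <- he_init(f, k, k)
      p[[paste0(br, "_bt")]] <- numeric(f)
      p[[paste0(br, "_ws")]] <- he_init(e, f * c_, f * c_)
      p[[paste0(br, "_bs")]] <- numeric(e)
    }
    p$cl_bng <- rep(1, e); p$cl_bnb <- numeric(e)
    p$cs_lng <- rep(1, e); p$cs_lnb <- numeric(e)
    if (config$fusion == "concat") {
      p$fu_w <- he_init(2 * e, e, 2 * e)
      p$fu_b <- numeric(e)
    }
    for (blk in seq_len(config$n_blocks)) {
      pre <- paste0("b", blk, "_")
      p[[paste0(pre, "ln1g")]] <- rep(1, e)
      p[[paste0(pre, "ln1b")]] <- numeric(e)
      p[[paste0(pre, "wI")]] <- he_init(e, config$n_heads, e)
      p[[paste0(pre, "WK")]] <- he_init(e, e, e)
      p[[paste0(pre, "WV")]] <- he_init(e, e, e)
      p[[paste0(pre, "Wo")]] <- he_init(e, e, e)
      p[[paste0(pre, "bo")]] <- numeric(e)
      p[[paste0(pre, "ln2g")]] <- rep(1, e)
      p[[paste0(pre, "ln2b")]] <- numeric(e)
      p[[paste0(pre, "W1")]] <- he_init(e, hid, e)
      p[[paste0(pre, "b1")]] <- numeric(hid)
      p[[paste0(pre, "W2")]] <- he_init(hid, e, hid)
      p[[paste0(pre, "b2")]] <- numeric(e)
    }
    if (config$use_reparam) {
      for (j in seq_len(config$conv_kernel_tokens)) {
        p[[paste0("rp_wc", j)]] <- he_init(e, e, e * config$conv_kernel_tokens)
      }
      p$rp_bc <- numeric(e)
      p$mu_lng <- rep(1, e); p$mu_lnb <- numeric(e)
      p$sg_lng <- rep(1, e); p$sg_lnb <- numeric(e)
    }
    p$hd_w <- he_init(e, config$n_classes, e)
    p$hd_b <- numeric(config$n_classes)
    p
  })
}

duformer_buffers <- function(config) {
  e <- config$embed_dim
  list(bn_mean = numeric(e), bn_var = rep(1, e))
}

# token-axis shift of a (B*T) x E token matrix by `shift` tokens
# (zero padding); shift = j - center of the conv kernel
shift_tokens <- function(x, B, shift) {
  if (shift == 0) return(x)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  if (shift > 0) {
    out[seq_len(n - shift * B), ] <- x[(shift * B + 1):n, , drop = FALSE]
  } else {
    out[(-shift * B + 1):n, ] <- x[seq_len(n + shift * B), , drop = FALSE]
  }
  out
}

# one pre-norm encoder block; returns output and cache
encoder_block_fwd <- function(x, p, pre, config, B, t_out, drop_mask = NULL) {
  cache <- list()
  if (config$use_smhsa) {
    ln1 <- layernorm_fwd(x, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    att <- smhsa_fwd(ln1$out,
                     list(wI = p[[paste0(pre, "wI")]],
                          WK = p[[paste0(pre, "WK")]],
                          WV = p[[paste0(pre, "WV")]],
                          Wo = p[[paste0(pre, "Wo")]],
                          bo = p[[paste0(pre, "bo")]]),
                     B, t_out, config$n_heads, config$attention_gate)
    a_out <- att$out
    if (!is.null(drop_mask)) a_out <- a_out * drop_mask$attn
    y <- x + a_out
    cache$ln1 <- ln1; cache$att <- att
  } else {
    y <- x
  }
  ln2 <- layernorm_fwd(y, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
  h_pre <- linear_fwd(ln2$out, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
  h <- relu_fwd(h_pre)
  f_out <- linear_fwd(h, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
  if (!is.null(drop_mask)) f_out <- f_out * drop_mask$ffn
  z <- y + f_out
  cache$ln2 <- ln2; cache$h_pre <- h_pre; cache$h <- h
  cache$y_in <- y
  cache$drop_mask <- drop_mask
  list(out = z, cache = cache)
}

encoder_block_bwd <- function(dz, cache, p, pre, config) {
  g <- list()
  dm <- cache$drop_mask
  df_out <- if (!is.null(dm)) dz * dm$ffn else dz
  lb2 <- linear_bwd(df_out, cache$h, p[[paste0(pre, "W2")]])
  g[[paste0(pre, "W2")]] <- lb2$dw; g[[paste0(pre, "b2")]] <- lb2$db
  dh <- relu_bwd(lb2$dx, cache$h_pre)
  lb1 <- linear_bwd(dh, cache$ln2$out, p[[paste0(pre, "W1")]])
  g[[paste0(pre, "W1")]] <- lb1$dw; g[[paste0(pre, "b1")]] <- lb1$db
  ln2b <- layernorm_bwd(lb1$dx, cache$ln2, p[[paste0(pre, "ln2g")]])
  g[[paste0(pre, "ln2g")]] <- ln2b$dg; g[[paste0(pre, "ln2b")]] <- ln2b$db
  dy <- dz + ln2b$dx
  if (config$use_smhsa) {
    da_out <- if (!is.null(dm)) dy * dm$attn else dy
    ab <- smhsa_bwd(da_out, cache$att,
                    list(wI = p[[paste0(pre, "wI")]],
                         WK = p[[paste0(pre, "WK")]],
                         WV = p[[paste0(pre, "WV")]],
                         Wo = p[[paste0(pre, "Wo")]],
                         bo = p[[paste0(pre, "bo")]]))
    g[[paste0(pre, "wI")]] <- ab$dwI; g[[paste0(pre, "WK")]] <- ab$dWK
    g[[paste0(pre, "WV")]] <- ab$dWV; g[[paste0(pre, "Wo")]] <- ab$dWo
    g[[paste0(pre, "bo")]] <- ab$dbo
    ln1b <- layernorm_bwd(ab$dx, cache$ln1, p[[paste0(pre, "ln1g")]])
    g[[paste0(pre, "ln1g")]] <- ln1b$dg; g[[paste0(pre, "ln1b")]] <- ln1b$db
    dx <- dy + ln1b$dx
  } else {
    dx <- dy
  }
  list(dx = dx, grads = g)
}

#' Forward pass of the DU-former network
#'
#' Composition: fuse(conv_large, conv_small) -> encoder blocks ->
#' Gaussian reparameterization -> linear classifier with softmax.
#'
#' @param params Parameter list from the trainer.
#' @param buffers Batch-norm running statistics.
#' @param x Input array (batch, channels, samples).
#' @param config A `duformer_config`.
#' @param mode `"train"` (batch statistics, sampled epsilon, dropout),
#'   `"deterministic"` (running statistics, S = mu) or `"mc"` (running
#'   statistics, sampled epsilon).
#' @param keep_cache Retain intermediates for the backward pass?
#' @return List with `probs`, `logits`, `mu`, `sigma`, `s` (the sampled
#'   embedding), updated `buffers`, and `cache` when requested.
#' @keywords internal
duformer_forward <- function(params, buffers, x, config,
                             mode = c("deterministic", "train", "mc"),
                             keep_cache = FALSE, precomp = NULL,
                             batch_idx = NULL) {
  mode <- match.arg(mode)
  training <- mode == "train"
  if (is.null(precomp)) {
    B <- dim(x)[1]
    ml <- NULL; ms_ <- NULL; tl <- NULL; ts_ <- NULL
  } else {
    B <- length(batch_idx)
    sl <- slice_patch_cols(precomp$large, batch_idx, precomp$n)
    ss <- slice_patch_cols(precomp$small, batch_idx, precomp$n)
    ml <- sl$mt; tl <- sl$t_out; ms_ <- ss$mt; ts_ <- ss$t_out
  }
  e <- config$embed_dim
  cache <- list(B = B)

  cl <- conv_branch_fwd(x, params$cl_wt, params$cl_bt,
                        params$cl_ws, params$cl_bs, config$stride_large,
                        mt = ml, t_out = tl, B = B, C = config$n_channels)
  t_out <- cl$t_out
  bn <- batchnorm_fwd(cl$out, params$cl_bng, params$cl_bnb,
                      buffers$bn_mean, buffers$bn_var, training)
  buffers$bn_mean <- bn$run_mean; buffers$bn_var <- bn$run_var
  zl <- relu_fwd(bn$out)

  cs <- conv_branch_fwd(x, params$cs_wt, params$cs_bt,
                        params$cs_ws, params$cs_bs, config$stride_small,
                        mt = ms_, t_out = ts_, B = B, C = config$n_channels)
  rs <- relu_fwd(cs$out)
  mp <- adaptive_maxpool_fwd(rs, B, cs$t_out, t_out)
  lns <- layernorm_fwd(mp$out, params$cs_lng, params$cs_lnb)
  zs <- lns$out

  if (config$fusion == "concat") {
    fused_in <- cbind(zl, zs)
    z <- linear_fwd(fused_in, params$fu_w, params$fu_b)
  } else {
    z <- zl + zs
  }

  drop_masks <- NULL
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    drop_masks <- lapply(seq_len(config$n_blocks), function(i) {
      list(attn = matrix(stats::rbinom(length(z), 1, keep), nrow(z)) / keep,
           ffn = matrix(stats::rbinom(length(z), 1, keep), nrow(z)) / keep)
    })
  }

  blk_caches <- vector("list", config$n_blocks)
  for (blk in seq_len(config$n_blocks)) {
    eb <- encoder_block_fwd(z, params, paste0("b", blk, "_"), config, B, t_out,
                            if (is.null(drop_masks)) NULL else drop_masks[[blk]])
    z <- eb$out
    blk_caches[[blk]] <- eb$cache
  }

  if (config$use_reparam) {
    kw <- config$conv_kernel_tokens
    center <- (kw + 1) %/% 2
    conv_t <- broadcast_rows(params$rp_bc, nrow(z))
    shifts <- vector("list", kw)
    for (j in seq_len(kw)) {
      shifts[[j]] <- shift_tokens(z, B, j - center)
      conv_t <- conv_t + shifts[[j]] %*% params[[paste0("rp_wc", j)]]
    }
    mu_pool <- avgpool_tokens(conv_t, B)
    lnm <- layernorm_fwd(mu_pool, params$mu_lng, params$mu_lnb)
    mu <- lnm$out
    sg_pool <- avgpool_tokens(z, B)
    lnsg <- layernorm_fwd(sg_pool, params$sg_lng, params$sg_lnb)
    sigma <- softplus(lnsg$out) + config$sigma_floor
    if (mode == "deterministic") {
      eps <- matrix(0, B, e)
    } else {
      eps <- matrix(stats::rnorm(B * e), B, e)
    }
    s <- mu + eps * sigma
  } else {
    s <- avgpool_tokens(z, B)
    mu <- s
    sigma <- matrix(0, B, e)
    eps <- NULL
    shifts <- NULL; lnm <- NULL; lnsg <- NULL
  }
  logits <- linear_fwd(s, params$hd_w, params$hd_b)
  probs <- softmax_rows(logits)

  if (keep_cache) {
    cache$cl <- cl; cache$bn <- bn; cache$zl_pre <- bn$out
    cache$cs <- cs; cache$rs_pre <- cs$out; cache$mp <- mp; cache$lns <- lns
    cache$zl <- zl; cache$zs <- zs
    cache$fused_in <- if (config$fusion == "concat") cbind(zl, zs) else NULL
    cache$blk <- blk_caches
    cache$t_out <- t_out
    cache$shifts <- shifts; cache$lnm <- lnm; cache$lnsg <- lnsg
    cache$z_enc <- if (config$use_reparam) NULL else NULL
    cache$eps <- eps; cache$sigma <- sigma; cache$mu <- mu; cache$s <- s
    cache$z_final <- z
  }
  list(probs = probs, logits = logits, mu = mu, sigma = sigma, s = s,
       buffers = buffers, cache = if (keep_cache) cache else NULL)
}

#' Backward pass of the DU-former network
#'
#' @param dlogits Gradient of the loss w.r.t. the logits.
#' @param dmu_extra,dsigma_extra Additional gradients entering at the
#'   Gaussian embedding (the KL regularizer); NULL for none.
#' @param cache Forward cache (`keep_cache = TRUE`).
#' @param params Parameter list.
#' @param config A `duformer_config`.
#' @return Named list of parameter gradients.
#' @keywords internal
duformer_backward <- function(dlogits, dmu_extra, dsigma_extra,
                              cache, params, config) {
  B <- cache$B
  t_out <- cache$t_out
  g <- list()
  hb <- linear_bwd(dlogits, cache$s, params$hd_w)
  g$hd_w <- hb$dw; g$hd_b <- hb$db
  ds <- hb$dx

  if (config$use_reparam) {
    dmu <- ds
    dsigma <- ds * cache$eps
    if (!is.null(dmu_extra)) dmu <- dmu + dmu_extra
    if (!is.null(dsigma_extra)) dsigma <- dsigma + dsigma_extra
    # sigma branch: softplus(LN(avgpool(z))) + floor
    dln_sg <- dsigma * sigmoid(cache$lnsg$out)
    sgb <- layernorm_bwd(dln_sg, cache$lnsg, params$sg_lng)
    g$sg_lng <- sgb$dg; g$sg_lnb <- sgb$db
    dz <- avgpool_tokens_bwd(sgb$dx, B, t_out)
    # mu branch: LN(avgpool(conv1d(z)))
    mub <- layernorm_bwd(dmu, cache$lnm, params$mu_lng)
    g$mu_lng <- mub$dg; g$mu_lnb <- mub$db
    dconv <- avgpool_tokens_bwd(mub$dx, B, t_out)
    kw <- config$conv_kernel_tokens
    center <- (kw + 1) %/% 2
    g$rp_bc <- colSums(dconv)
    for (j in seq_len(kw)) {
      g[[paste0("rp_wc", j)]] <- crossprod(cache$shifts[[j]], dconv)
      dz <- dz + shift_tokens(dconv %*% t(params[[paste0("rp_wc", j)]]),
                              B, -(j - center))
    }
  } else {
    dz <- avgpool_tokens_bwd(ds, B, t_out)
  }

  for (blk in rev(seq_len(config$n_blocks))) {
    eb <- encoder_block_bwd(dz, cache$blk[[blk]], params,
                            paste0("b", blk, "_"), config)
    dz <- eb$dx
    g <- c(g, eb$grads)
  }

  if (config$fusion == "concat") {
    fb <- linear_bwd(dz, cache$fused_in, params$fu_w)
    g$fu_w <- fb$dw; g$fu_b <- fb$db
    e <- config$embed_dim
    dzl <- fb$dx[, seq_len(e), drop = FALSE]
    dzs <- fb$dx[, e + seq_len(e), drop = FALSE]
  } else {
    dzl <- dz
    dzs <- dz
  }

  # small branch: LN <- maxpool <- ReLU <- conv
  lnsb <- layernorm_bwd(dzs, cache$lns, params$cs_lng)
  g$cs_lng <- lnsb$dg; g$cs_lnb <- lnsb$db
  dmp <- adaptive_maxpool_bwd(lnsb$dx, cache$mp)
  drs <- relu_bwd(dmp, cache$rs_pre)
  csb <- conv_branch_bwd(drs, cache$cs, params$cs_wt, params$cs_ws)
  g$cs_wt <- csb$dwt; g$cs_bt <- csb$dbt
  g$cs_ws <- csb$dws; g$cs_bs <- csb$dbs

  # large branch: ReLU <- BN <- conv
  dbn_out <- relu_bwd(dzl, cache$zl_pre)
  bnb <- batchnorm_bwd(dbn_out, cache$bn, params$cl_bng)
  g$cl_bng <- bnb$dg; g$cl_bnb <- bnb$db
  clb <- conv_branch_bwd(bnb$dx, cache$cl, params$cl_wt, params$cl_ws)
  g$cl_wt <- clb$dwt; g$cl_bt <- clb$dbt
  g$cl_ws <- clb$dws; g$cl_bs <- clb$dbs
  g
}

#' Training loss: cross-entropy plus KL regularizer
#'
#' `CE(probs, labels) + lambda * mean(KL(N(mu, diag(sigma^2)) || N(0, I)))`.
#' With `kl_weight = 0` this is plain cross-entropy.
#'
#' @param probs Matrix of predicted class probabilities (rows sum to 1).
#' @param labels Integer labels in \{0, 1\}.
#' @param mu,sigma Gaussian embedding parameters (NULL to skip the KL
#'   term).
#' @param kl_weight Regularizer weight lambda.
#' @return Scalar loss.
#' @export
duformer_loss <- function(probs, labels, mu = NULL, sigma = NULL,
                          kl_weight = 1e-4) {
  l <- cross_entropy(probs, labels)
  if (!is.null(mu) && !is.null(sigma) && kl_weight > 0) {
    if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
    l <- l + kl_weight * mean(kl_standard_normal(mu, sigma))
  }
  l
}

#' Separable multi-head self-attention on a token tensor
#'
#' Functional form of the attention used in the encoder blocks: per head,
#' context scores are a softmax over tokens of the scalar projection I;
#' the context vector is the score-weighted sum of the K rows; each
#' output row is the gated V row modulated elementwise by the context
#' vector. Cost is linear in the token count (no token x token matrix).
#'
#' @param x Array (batch, tokens, embed_dim).
#' @param w_i Matrix embed_dim x n_heads (context logit projection).
#' @param w_k,w_v Matrices embed_dim x embed_dim (head-blocked K and V
#'   projections).
#' @param w_out Output projection embed_dim x embed_dim.
#' @param b_out Output bias (length embed_dim).
#' @param n_heads Number of heads (embed_dim must be divisible by it).
#' @param gate `"relu"` (default) or `"sigmoid"` gating of V.
#' @return Array (batch, tokens, embed_dim).
#' @export
separable_attention <- function(x, w_i, w_k, w_v, w_out, b_out,
                                n_heads = 1, gate = "relu") {
  stopifnot(length(dim(x)) == 3)
  d <- dim(x)
  e <- d[3]
  if (e %% n_heads != 0) stop("embed_dim must be divisible by n_heads",
                              call. = FALSE)
  xm <- matrix(x, d[1] * d[2], e)
  out <- smhsa_fwd(xm, list(wI = w_i, WK = w_k, WV = w_v, Wo = w_out,
                            bo = b_out),
                   d[1], d[2], n_heads, gate)$out
  array(out, d)
}

#' Draw samples from a Gaussian feature embedding
#'
#' The reparameterization step in functional form: `S = mu + eps * sigma`
#' with `eps ~ N(0, I)`, drawn row-wise. This is the same sampling rule the
#' network applies in train/Monte-Carlo modes.
#'
#' @param mu,sigma Numeric vectors (length d) or matrices; `sigma > 0`.
#' @param n_draws Number of samples.
#' @return Matrix `n_draws` x d of samples.
#' @export
sample_gaussian_embedding <- function(mu, sigma, n_draws = 1) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  d <- length(mu)
  eps <- matrix(stats::rnorm(n_draws * d), n_draws, d)
  sweep(eps * matrix(sigma, n_draws, d, byrow = TRUE), 2, mu, "+")
}
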