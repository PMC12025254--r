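# Transparent baseline architectures sharing DU-former's input/output
# contract (array (B,C,N) in, class probabilities out) for the comparison
# harness: a two-conv-layer CNN, a depthwise-separable EEGNet-style
# network, and DU-former's front end with standard quadratic-attention
# Transformer blocks ("plain_transformer").

## ---- cnn --------------------------------------------------------------

cnn_init <- function(config) {
  with_seed(derive_seed(config$seed, "cnn-init"), {
    f <- config$n_filters; k <- config$temporal_kernel
    c_ <- config$n_channels; e <- config$embed_dim
    list(
      wt = he_init(f, k, k), bt = numeric(f),
      ws = he_init(e, f * c_, f * c_), bs = numeric(e),
      bng = rep(1, e), bnb = numeric(e),
      hd_w = he_init(e, config$n_classes, e), hd_b = numeric(config$n_classes)
    )
  })
}

cnn_forward <- function(params, buffers, x, config, mode, keep_cache = FALSE,
                        precomp = NULL, batch_idx = NULL) {
  training <- mode == "train"
  if (is.null(precomp)) {
    B <- dim(x)[1]; ml <- NULL; tl <- NULL
  } else {
    B <- length(batch_idx)
    sl <- slice_patch_cols(precomp$large, batch_idx, precomp$n)
    ml <- sl$mt; tl <- sl$t_out
  }
  cv <- conv_branch_fwd(x, params$wt, params$bt, params$ws, params$bs,
                        config$stride_large, mt = ml, t_out = tl, B = B,
                        C = config$n_channels)
  bn <- batchnorm_fwd(cv$out, params$bng, params$bnb,
                      buffers$bn_mean, buffers$bn_var, training)
  buffers$bn_mean <- bn$run_mean; buffers$bn_var <- bn$run_var
  z <- relu_fwd(bn$out)
  pooled <- avgpool_tokens(z, B)
  logits <- linear_fwd(pooled, params$hd_w, params$hd_b)
  cache <- if (keep_cache) {
    list(B = B, cv = cv, bn = bn, z_pre = bn$out, pooled = pooled,
         t_out = cv$t_out)
  }
  list(probs = softmax_rows(logits), logits = logits,
       mu = NULL, sigma = NULL, s = pooled, buffers = buffers, cache = cache)
}

cnn_backward <- function(dlogits, dmu_extra, dsigma_extra, cache, params,
                         config) {
  hb <- linear_bwd(dlogits, cache$pooled, params$hd_w)
  dz <- avgpool_tokens_bwd(hb$dx, cache$B, cache$t_out)
  dbn_out <- relu_bwd(dz, cache$z_pre)
  bnb <- batchnorm_bwd(dbn_out, cache$bn, params$bng)
  cb <- conv_branch_bwd(bnb$dx, cache$cv, params$wt, params$ws)
  list(wt = cb$dwt, bt = cb$dbt, ws = cb$dws, bs = cb$dbs,
       bng = bnb$dg, bnb = bnb$db, hd_w = hb$dw, hd_b = hb$db)
}

## ---- eegnet-style ------------------------------------------------------

eegnet_init <- function(config) {
  with_seed(derive_seed(config$seed, "eegnet-init"), {
    f <- config$n_filters; k <- config$temporal_kernel
    c_ <- config$n_channels; e <- config$embed_dim
    list(
      wt = he_init(f, k, k), bt = numeric(f),
      wdw = he_init(f, c_, c_),                 # depthwise spatial filter
      bng = rep(1, f), bnb = numeric(f),
      wpw = he_init(f, e, f), bpw = numeric(e), # pointwise (separable) conv
      hd_w = he_init(e, config$n_classes, e), hd_b = numeric(config$n_classes)
    )
  })
}

eegnet_forward <- function(params, buffers, x, config, mode,
                           keep_cache = FALSE, precomp = NULL,
                           batch_idx = NULL) {
  training <- mode == "train"
  d <- dim(x); B <- d[1]; c_ <- d[2]
  k <- ncol(params$wt)
  ic <- im2col_temporal(x, k, config$stride_large)
  t_out <- ic$t_out
  y <- ic$m %*% t(params$wt) + broadcast_rows(params$bt, nrow(ic$m))
  f <- ncol(y)
  yarr <- array(y, c(B, c_, t_out, f))
  # depthwise spatial: per filter f, weighted sum over channels
  z <- matrix(0, B * t_out, f)
  for (ch in seq_len(c_)) {
    z <- z + matrix(yarr[, ch, , ], B * t_out, f) *
      broadcast_rows(params$wdw[, ch], B * t_out)
  }
  bn <- batchnorm_fwd(z, params$bng, params$bnb,
                      buffers$bn_mean, buffers$bn_var, training)
  buffers$bn_mean <- bn$run_mean; buffers$bn_var <- bn$run_var
  a <- relu_fwd(bn$out)
  pw_pre <- linear_fwd(a, params$wpw, params$bpw)
  pw <- relu_fwd(pw_pre)
  pooled <- avgpool_tokens(pw, B)
  logits <- linear_fwd(pooled, params$hd_w, params$hd_b)
  cache <- if (keep_cache) {
    list(B = B, C = c_, m = ic$m, yarr = yarr, bn = bn, z_pre = bn$out,
         a = a, pw_pre = pw_pre, pooled = pooled, t_out = t_out, f = f)
  }
  list(probs = softmax_rows(logits), logits = logits,
       mu = NULL, sigma = NULL, s = pooled, buffers = buffers, cache = cache)
}

eegnet_backward <- function(dlogits, dmu_extra, dsigma_extra, cache, params,
                            config) {
  B <- cache$B; c_ <- cache$C; t_out <- cache$t_out; f <- cache$f
  hb <- linear_bwd(dlogits, cache$pooled, params$hd_w)
  dpw <- avgpool_tokens_bwd(hb$dx, B, t_out)
  dpw_pre <- relu_bwd(dpw, cache$pw_pre)
  pb <- linear_bwd(dpw_pre, cache$a, params$wpw)
  da <- relu_bwd(pb$dx, cache$z_pre)
  bnb <- batchnorm_bwd(da, cache$bn, params$bng)
  dz <- bnb$dx
  dwdw <- matrix(0, f, c_)
  dy <- array(0, c(B, c_, t_out, f))
  for (ch in seq_len(c_)) {
    ymat_ch <- matrix(cache$yarr[, ch, , ], B * t_out, f)
    dwdw[, ch] <- colSums(dz * ymat_ch)
    dy[, ch, , ] <- array(dz * broadcast_rows(params$wdw[, ch], B * t_out),
                          c(B, t_out, f))
  }
  dy_mat <- matrix(aperm(dy, c(1, 2, 3, 4)), B * c_ * t_out, f)
  dwt <- crossprod(dy_mat, cache$m)
  list(wt = dwt, bt = colSums(dy_mat), wdw = dwdw,
       bng = bnb$dg, bnb = bnb$db, wpw = pb$dw, bpw = pb$db,
       hd_w = hb$dw, hd_b = hb$db)
}

## ---- plain transformer -------------------------------------------------

plaintf_init <- function(config) {
  with_seed(derive_seed(config$seed, "plaintf-init"), {
    f <- config$n_filters; k <- config$temporal_kernel
    c_ <- config$n_channels; e <- config$embed_dim
    hid <- e * config$ffn_expansion
    p <- list(
      wt = he_init(f, k, k), bt = numeric(f),
      ws = he_init(e, f * c_, f * c_), bs = numeric(e),
      bng = rep(1, e), bnb = numeric(e)
    )
    for (blk in seq_len(config$n_blocks)) {
      pre <- paste0("b", blk, "_")
      p[[paste0(pre, "ln1g")]] <- rep(1, e)
      p[[paste0(pre, "ln1b")]] <- numeric(e)
      p[[paste0(pre, "WQ")]] <- he_init(e, e, e)
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
    p$hd_w <- he_init(e, config$n_classes, e)
    p$hd_b <- numeric(config$n_classes)
    p
  })
}

# standard softmax attention (token x token matrix), looped over batch and
# head; used only by the plain-transformer baseline
mhsa_fwd <- function(x, p, B, t_out, n_heads) {
  e <- ncol(x)
  dh <- e / n_heads
  q <- x %*% p$WQ; k <- x %*% p$WK; v <- x %*% p$WV
  y <- matrix(0, nrow(x), e)
  attn <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(t_out) - 1L) * B
    for (h in seq_len(n_heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      s <- tcrossprod(q[rows, cols, drop = FALSE],
                      k[rows, cols, drop = FALSE]) / sqrt(dh)
      s <- exp(s - apply(s, 1, max))
      a <- s / rowSums(s)
      attn[[(b - 1L) * n_heads + h]] <- a
      y[rows, cols] <- a %*% v[rows, cols, drop = FALSE]
    }
  }
  out <- y %*% p$Wo + broadcast_rows(p$bo, nrow(y))
  list(out = out, x = x, q = q, k = k, v = v, y = y, attn = attn,
       B = B, t_out = t_out, n_heads = n_heads, dh = dh)
}

mhsa_bwd <- function(dout, cache, p) {
  B <- cache$B; t_out <- cache$t_out; nh <- cache$n_heads; dh <- cache$dh
  dy <- dout %*% t(p$Wo)
  dWo <- crossprod(cache$y, dout)
  dbo <- colSums(dout)
  dq <- matrix(0, nrow(dy), ncol(dy))
  dk <- dq; dv <- dq
  for (b in seq_len(B)) {
    rows <- b + (seq_len(t_out) - 1L) * B
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      a <- cache$attn[[(b - 1L) * nh + h]]
      dyb <- dy[rows, cols, drop = FALSE]
      dv[rows, cols] <- crossprod(a, dyb)
      da <- tcrossprod(dyb, cache$v[rows, cols, drop = FALSE])
      ds <- a * (da - rowSums(a * da))      # softmax rows backward
      dq[rows, cols] <- ds %*% cache$k[rows, cols, drop = FALSE] / sqrt(dh)
      dk[rows, cols] <- crossprod(ds, cache$q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  list(dx = dq %*% t(p$WQ) + dk %*% t(p$WK) + dv %*% t(p$WV),
       dWQ = crossprod(cache$x, dq), dWK = crossprod(cache$x, dk),
       dWV = crossprod(cache$x, dv), dWo = dWo, dbo = dbo)
}

plaintf_forward <- function(params, buffers, x, config, mode,
                            keep_cache = FALSE, precomp = NULL,
                            batch_idx = NULL) {
  training <- mode == "train"
  if (is.null(precomp)) {
    B <- dim(x)[1]; ml <- NULL; tl <- NULL
  } else {
    B <- length(batch_idx)
    sl <- slice_patch_cols(precomp$large, batch_idx, precomp$n)
    ml <- sl$mt; tl <- sl$t_out
  }
  cv <- conv_branch_fwd(x, params$wt, params$bt, params$ws, params$bs,
                        config$stride_large, mt = ml, t_out = tl, B = B,
                        C = config$n_channels)
  t_out <- cv$t_out
  bn <- batchnorm_fwd(cv$out, params$bng, params$bnb,
                      buffers$bn_mean, buffers$bn_var, training)
  buffers$bn_mean <- bn$run_mean; buffers$bn_var <- bn$run_var
  z <- relu_fwd(bn$out)
  z_pre <- bn$out
  blk_caches <- vector("list", config$n_blocks)
  for (blk in seq_len(config$n_blocks)) {
    pre <- paste0("b", blk, "_")
    ln1 <- layernorm_fwd(z, params[[paste0(pre, "ln1g")]],
                         params[[paste0(pre, "ln1b")]])
    att <- mhsa_fwd(ln1$out,
                    list(WQ = params[[paste0(pre, "WQ")]],
                         WK = params[[paste0(pre, "WK")]],
                         WV = params[[paste0(pre, "WV")]],
                         Wo = params[[paste0(pre, "Wo")]],
                         bo = params[[paste0(pre, "bo")]]),
                    B, t_out, config$n_heads)
    y <- z + att$out
    ln2 <- layernorm_fwd(y, params[[paste0(pre, "ln2g")]],
                         params[[paste0(pre, "ln2b")]])
    h_pre <- linear_fwd(ln2$out, params[[paste0(pre, "W1")]],
                        params[[paste0(pre, "b1")]])
    h <- relu_fwd(h_pre)
    f_out <- linear_fwd(h, params[[paste0(pre, "W2")]],
                        params[[paste0(pre, "b2")]])
    z_new <- y + f_out
    blk_caches[[blk]] <- list(ln1 = ln1, att = att, ln2 = ln2,
                              h_pre = h_pre, h = h)
    z <- z_new
  }
  pooled <- avgpool_tokens(z, B)
  logits <- linear_fwd(pooled, params$hd_w, params$hd_b)
  cache <- if (keep_cache) {
    list(B = B, cv = cv, bn = bn, z_pre = z_pre, blk = blk_caches,
         pooled = pooled, t_out = t_out)
  }
  list(probs = softmax_rows(logits), logits = logits,
       mu = NULL, sigma = NULL, s = pooled, buffers = buffers, cache = cache)
}

plaintf_backward <- function(dlogits, dmu_extra, dsigma_extra, cache, params,
                             config) {
  B <- cache$B; t_out <- cache$t_out
  g <- list()
  hb <- linear_bwd(dlogits, cache$pooled, params$hd_w)
  g$hd_w <- hb$dw; g$hd_b <- hb$db
  dz <- avgpool_tokens_bwd(hb$dx, B, t_out)
  for (blk in rev(seq_len(config$n_blocks))) {
    pre <- paste0("b", blk, "_")
    bc <- cache$blk[[blk]]
    lb2 <- linear_bwd(dz, bc$h, params[[paste0(pre, "W2")]])
    g[[paste0(pre, "W2")]] <- lb2$dw; g[[paste0(pre, "b2")]] <- lb2$db
    dh <- relu_bwd(lb2$dx, bc$h_pre)
    lb1 <- linear_bwd(dh, bc$ln2$out, params[[paste0(pre, "W1")]])
    g[[paste0(pre, "W1")]] <- lb1$dw; g[[paste0(pre, "b1")]] <- lb1$db
    ln2b <- layernorm_bwd(lb1$dx, bc$ln2, params[[paste0(pre, "ln2g")]])
    g[[paste0(pre, "ln2g")]] <- ln2b$dg; g[[paste0(pre, "ln2b")]] <- ln2b$db
    dy <- dz + ln2b$dx
    ab <- mhsa_bwd(dy, bc$att,
                   list(WQ = params[[paste0(pre, "WQ")]],
                        WK = params[[paste0(pre, "WK")]],
                        WV = params[[paste0(pre, "WV")]],
                        Wo = params[[paste0(pre, "Wo")]],
                        bo = params[[paste0(pre, "bo")]]))
    g[[paste0(pre, "WQ")]] <- ab$dWQ; g[[paste0(pre, "WK")]] <- ab$dWK
    g[[paste0(pre, "WV")]] <- ab$dWV; g[[paste0(pre, "Wo")]] <- ab$dWo
    g[[paste0(pre, "bo")]] <- ab$dbo
    ln1b <- layernorm_bwd(ab$dx, bc$ln1, params[[paste0(pre, "ln1g")]])
    g[[paste0(pre, "ln1g")]] <- ln1b$dg; g[[paste0(pre, "ln1b")]] <- ln1b$db
    dz <- dy + ln1b$dx
  }
  dbn_out <- relu_bwd(dz, cache$z_pre)
  bnb <- batchnorm_bwd(dbn_out, cache$bn, params$bng)
  g$bng <- bnb$dg; g$bnb <- bnb$db
  cb <- conv_branch_bwd(bnb$dx, cache$cv, params$wt, params$ws)
  g$wt <- cb$dwt; g$bt <- cb$dbt; g$ws <- cb$dws; g$bs <- cb$dbs
  g
}

## ---- factory -----------------------------------------------------------

#' Baseline and DU-former model constructors
#'
#' Returns the init/forward/backward triple for a named architecture, all
#' sharing the DU-former input/output contract so the comparison harness
#' can train them interchangeably.
#'
#' @param name One of `"duformer"`, `"cnn"`, `"eegnet_like"`,
#'   `"plain_transformer"`.
#' @return List with elements `name`, `init`, `buffers`, `forward`,
#'   `backward`, `has_reparam`.
#' @export
baseline_factory <- function(name) {
  switch(
    name,
    duformer = list(
      name = "duformer", init = duformer_init, buffers = duformer_buffers,
      forward = duformer_forward, backward = duformer_backward,
      has_reparam = TRUE,
      precompute = function(x, config) {
        precompute_patches(x, config$temporal_kernel,
                           list(large = config$stride_large,
                                small = config$stride_small))
      }
    ),
    cnn = list(
      name = "cnn", init = cnn_init, buffers = duformer_buffers,
      forward = cnn_forward, backward = cnn_backward, has_reparam = FALSE,
      precompute = function(x, config) {
        precompute_patches(x, config$temporal_kernel,
                           list(large = config$stride_large))
      }
    ),
    eegnet_like = list(
      name = "eegnet_like", init = eegnet_init,
      buffers = function(config) list(bn_mean = numeric(config$n_filters),
                                      bn_var = rep(1, config$n_filters)),
      forward = eegnet_forward, backward = eegnet_backward,
      has_reparam = FALSE, precompute = NULL
    ),
    plain_transformer = list(
      name = "plain_transformer", init = plaintf_init,
      buffers = duformer_buffers,
      forward = plaintf_forward, backward = plaintf_backward,
      has_reparam = FALSE,
      precompute = function(x, config) {
        precompute_patches(x, config$temporal_kernel,
                           list(large = config$stride_large))
      }
    ),
    stop("unknown model '", name, "'; choose one of duformer, cnn, ",
         "eegnet_like, plain_transformer", call. = FALSE)
  )
}
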