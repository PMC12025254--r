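# Neural-network primitives with explicit forward/backward passes.
#
# Layout conventions used throughout:
#   * raw input x: array (B, C, N)  — batch, channels, samples
#   * token matrices: (B*T) x E with the batch index fastest, i.e. row
#     r = b + (t-1)*B, so dim(x) <- c(B, T, E) recovers the tensor view.
# All heavy lifting is expressed as BLAS matrix products; backward passes
# reuse cached forward intermediates.

broadcast_rows <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

## ---- dense -----------------------------------------------------------

linear_fwd <- function(x, w, b) x %*% w + broadcast_rows(b, nrow(x))

linear_bwd <- function(dout, x, w) {
  list(dx = dout %*% t(w), dw = crossprod(x, dout), db = colSums(dout))
}

## ---- normalization ---------------------------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = xhat * broadcast_rows(g, nrow(x)) + broadcast_rows(b, nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- dout * broadcast_rows(g, nrow(dout))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

batchnorm_fwd <- function(x, g, b, run_mean, run_var, training,
                          momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - broadcast_rows(mu, nrow(x))) * broadcast_rows(inv, nrow(x))
  list(out = xhat * broadcast_rows(g, nrow(x)) + broadcast_rows(b, nrow(x)),
       xhat = xhat, inv = inv, run_mean = run_mean, run_var = run_var)
}

batchnorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dout)
  dxhat <- dout * broadcast_rows(g, n)
  dx <- broadcast_rows(cache$inv, n) *
    (dxhat - broadcast_rows(colMeans(dxhat), n) -
       xhat * broadcast_rows(colMeans(dxhat * xhat), n))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

## ---- activations -----------------------------------------------------

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}
relu_bwd <- function(dout, x_pre) dout * (x_pre > 0)

## ---- convolution front end -------------------------------------------

# im2col for the 1 x k temporal kernel: returns ((B*C*T) x k) patch matrix
# with rows ordered (b, c, t), b fastest.
im2col_temporal <- function(x, k, stride) {
  d <- dim(x)                       # (B, C, N)
  bc <- d[1] * d[2]
  n <- d[3]
  t_out <- floor((n - k) / stride) + 1
  xmat <- x
  dim(xmat) <- c(bc, n)
  idx <- as.vector(outer((seq_len(t_out) - 1L) * stride, seq_len(k), "+"))
  m <- xmat[, idx]                  # (B*C) x (T*k), t fastest within k
  dim(m) <- c(bc * t_out, k)
  list(m = m, t_out = t_out)
}

# Patch matrix for the composed temporal+spatial convolution: rows (b, t),
# columns (c, j) with c fastest.
im2col_patches <- function(x, k, stride) {
  d <- dim(x)                       # (B, C, N)
  t_out <- floor((d[3] - k) / stride) + 1
  idx <- as.vector(outer((seq_len(t_out) - 1L) * stride, seq_len(k), "+"))
  xmat <- x
  dim(xmat) <- c(d[1] * d[2], d[3])
  m <- xmat[, idx]                  # (B*C, T*k)
  dim(m) <- c(d[1], d[2], t_out, k)
  m <- aperm(m, c(1, 3, 2, 4))      # (B, T, C, k)
  dim(m) <- c(d[1] * t_out, d[2] * k)
  list(m = m, t_out = t_out)
}

# Temporal (1 x k, stride, F filters) then spatial (C x 1, E outputs)
# convolution collapsing the electrode axis: x (B,C,N) -> (B*T) x E token
# matrix. The factorized kernels are contracted into one combined kernel
# Q[(c,j), e] = sum_f ws[e, (f,c)] wt[f, j]; the composition is exact and
# needs a single patch-matrix product. The temporal bias is omitted: it is
# constant over time, so the spatial bias absorbs it.
conv_branch_fwd <- function(x, wt, bt, ws, bs, stride, mt = NULL,
                            t_out = NULL, B = NULL, C = NULL) {
  f <- nrow(wt); k <- ncol(wt)
  if (is.null(mt)) {
    d <- dim(x)
    B <- d[1]; C <- d[2]
    ic <- im2col_patches(x, k, stride)
  } else {
    ic <- list(mt = mt, t_out = t_out)
  }
  wsa <- ws
  dim(wsa) <- c(nrow(ws), f, C)                 # (E, F, C)
  q <- matrix(0, C * k, nrow(ws))               # combined kernel, cols e
  for (cc in seq_len(C)) {
    rows <- cc + C * (seq_len(k) - 1L)
    q[rows, ] <- crossprod(wt, t(wsa[, , cc]))  # k x E
  }
  z <- if (is.null(ic$mt)) {
    ic$m %*% q
  } else {
    crossprod(ic$mt, q)
  }
  z <- z + broadcast_rows(bs, nrow(z))
  list(out = z, m = ic$m, mt = ic$mt, t_out = ic$t_out,
       B = B, C = C, f = f, k = k)
}

conv_branch_bwd <- function(dz, cache, wt, ws) {
  C <- cache$C; f <- cache$f; k <- cache$k
  e <- ncol(dz)
  dq <- if (is.null(cache$mt)) {
    crossprod(cache$m, dz)                      # (C*k) x E
  } else {
    cache$mt %*% dz
  }
  dim(dq) <- c(C, k, e)
  wsa <- ws
  dim(wsa) <- c(e, f, C)
  dwt <- matrix(0, f, k)
  dws <- array(0, c(e, f, C))
  for (cc in seq_len(C)) {
    dq_c <- matrix(dq[cc, , ], k, e)            # k x E
    dwt <- dwt + t(wsa[, , cc]) %*% t(dq_c)     # F x k
    dws[, , cc] <- t(dq_c) %*% t(wt)            # E x F
  }
  dim(dws) <- c(e, f * C)
  list(dwt = dwt, dbt = numeric(f), dws = dws, dbs = colSums(dz))
}

# Precompute whole-dataset patch matrices so the training loop only has to
# slice columns per minibatch (the patch matrix depends on data alone).
# Stored transposed ((C*k) x (B*T)) so slicing copies whole columns and the
# forward product consumes the transpose directly via crossprod.
precompute_patches <- function(x, k, strides) {
  uniq <- unique(unlist(strides))
  built <- lapply(uniq, function(s) {
    ic <- im2col_patches(x, k, s)
    list(mt = t(ic$m), t_out = ic$t_out)
  })
  out <- lapply(strides, function(s) built[[match(s, uniq)]])
  names(out) <- names(strides)
  out$n <- dim(x)[1]
  out
}

# columns of a precomputed (transposed) patch matrix belonging to a batch,
# ordered (b, t) with b fastest
slice_patch_cols <- function(pc_entry, batch_idx, n) {
  t_out <- pc_entry$t_out
  cols <- as.vector(outer(batch_idx, (seq_len(t_out) - 1L) * n, "+"))
  list(mt = pc_entry$mt[, cols, drop = FALSE], t_out = t_out)
}

## ---- pooling ---------------------------------------------------------

# Adaptive max pooling over the token axis: (B*Ts) x E -> (B*T) x E with T
# output windows covering the input evenly (PyTorch-style boundaries).
adaptive_maxpool_fwd <- function(x, B, t_in, t_out) {
  e <- ncol(x)
  lo <- floor((seq_len(t_out) - 1) * t_in / t_out) + 1
  hi <- ceiling(seq_len(t_out) * t_in / t_out)
  out <- matrix(0, B * t_out, e)
  argmax <- matrix(0L, B * t_out, e)   # token index of each max
  for (i in seq_len(t_out)) {
    rows_i <- (i - 1L) * B + seq_len(B)
    cur <- x[(lo[i] - 1L) * B + seq_len(B), , drop = FALSE]
    idx <- matrix(lo[i], B, e)
    if (hi[i] > lo[i]) {
      for (tt in (lo[i] + 1L):hi[i]) {
        cand <- x[(tt - 1L) * B + seq_len(B), , drop = FALSE]
        better <- cand > cur
        cur[better] <- cand[better]
        idx[better] <- tt
      }
    }
    out[rows_i, ] <- cur
    argmax[rows_i, ] <- idx
  }
  list(out = out, argmax = argmax, lo = lo, hi = hi, t_in = t_in, B = B)
}

adaptive_maxpool_bwd <- function(dout, cache) {
  B <- cache$B
  e <- ncol(dout)
  t_out <- nrow(dout) / B
  dx <- matrix(0, B * cache$t_in, e)
  col_off <- (seq_len(e) - 1L) * (B * cache$t_in)
  for (i in seq_len(t_out)) {
    rows_i <- (i - 1L) * B + seq_len(B)
    idx <- cache$argmax[rows_i, , drop = FALSE]       # token indices, B x E
    lin <- (idx - 1L) * B + seq_len(B) +              # row within column
      matrix(col_off, B, e, byrow = TRUE)
    dx[lin] <- dx[lin] + dout[rows_i, , drop = FALSE]
  }
  dx
}

# Mean over the token axis: (B*T) x E -> B x E.
avgpool_tokens <- function(x, B) {
  t_out <- nrow(x) / B
  arr <- array(x, c(B, t_out, ncol(x)))
  colSums(aperm(arr, c(2, 1, 3))) / t_out
}

avgpool_tokens_bwd <- function(dout, B, t_out) {
  dout[rep(seq_len(B), t_out), , drop = FALSE] / t_out
}

# broadcast a B x E matrix to (B*T) x E token rows
expand_tokens <- function(m, t_out) m[rep(seq_len(nrow(m)), t_out), , drop = FALSE]

# sum token rows back to B x E
reduce_tokens <- function(x, B) {
  t_out <- nrow(x) / B
  arr <- array(x, c(B, t_out, ncol(x)))
  colSums(aperm(arr, c(2, 1, 3)))
}

## ---- separable multi-head self-attention ------------------------------

# Softmax over the token axis of a (B*T) x H matrix; returns same shape.
token_softmax <- function(i_mat, B, t_out) {
  h <- ncol(i_mat)
  arr <- array(i_mat, c(B, t_out, h))
  m <- arr[, 1, , drop = FALSE]
  if (t_out > 1) for (tt in 2:t_out) m <- pmax(m, arr[, tt, , drop = FALSE])
  m <- array(m, c(B, 1, h))[, rep(1, t_out), , drop = FALSE]
  ex <- exp(arr - m)
  denom <- colSums(aperm(ex, c(2, 1, 3)))             # B x H
  denom_full <- array(denom, c(B, h))[rep(seq_len(B), t_out), ]
  matrix(ex, B * t_out, h) / denom_full
}

smhsa_fwd <- function(x, p, B, t_out, n_heads, gate = "relu") {
  e <- ncol(x)
  dh <- e / n_heads
  i_mat <- x %*% p$wI                                  # (B*T) x H
  a <- token_softmax(i_mat, B, t_out)                  # context scores
  k <- x %*% p$WK
  v <- x %*% p$WV
  ae <- a[, rep(seq_len(n_heads), each = dh), drop = FALSE]
  ctx <- reduce_tokens(ae * k, B)                      # B x E context vector
  ctxb <- expand_tokens(ctx, t_out)
  r <- if (gate == "sigmoid") sigmoid(v) else relu_fwd(v)
  y <- r * ctxb
  out <- y %*% p$Wo + broadcast_rows(p$bo, nrow(y))
  list(out = out, x = x, a = a, ae = ae, k = k, v = v, r = r,
       ctxb = ctxb, y = y, gate = gate, B = B, t_out = t_out,
       n_heads = n_heads, dh = dh)
}

smhsa_bwd <- function(dout, cache, p) {
  B <- cache$B; t_out <- cache$t_out; h <- cache$n_heads; dh <- cache$dh
  dy <- dout %*% t(p$Wo)
  dWo <- crossprod(cache$y, dout)
  dbo <- colSums(dout)
  dr <- dy * cache$ctxb
  dv <- if (cache$gate == "sigmoid") {
    dr * cache$r * (1 - cache$r)
  } else {
    dr * (cache$v > 0)
  }
  dctx <- reduce_tokens(dy * cache$r, B)               # B x E
  dctxb <- expand_tokens(dctx, t_out)
  dk <- cache$ae * dctxb
  u <- cache$k * dctxb
  da <- matrix(colSums(aperm(array(u, c(nrow(u), dh, h)), c(2, 1, 3))),
               nrow(u), h)                             # rowsums per head
  # softmax (over tokens) backward, per (b, head)
  s <- reduce_tokens(cache$a * da, B)                  # B x H
  di <- cache$a * (da - expand_tokens(s, t_out))
  dx <- di %*% t(p$wI) + dk %*% t(p$WK) + dv %*% t(p$WV)
  list(dx = dx,
       dwI = crossprod(cache$x, di),
       dWK = crossprod(cache$x, dk),
       dWV = crossprod(cache$x, dv),
       dWo = dWo, dbo = dbo)
}

## ---- optimizer --------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && !is.null(dim(params[[nm]]))) {
      step <- step + lr * weight_decay * params[[nm]]  # decoupled decay
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

## ---- losses -----------------------------------------------------------

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  ex / rowSums(ex)
}

cross_entropy <- function(probs, labels) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), labels + 1L)
  -mean(log(pmax(probs[idx], 1e-12)))
}

# dL/dlogits for mean cross-entropy with softmax outputs
cross_entropy_grad <- function(probs, labels) {
  n <- nrow(probs)
  y <- matrix(0, n, ncol(probs))
  y[cbind(seq_len(n), labels + 1L)] <- 1
  (probs - y) / n
}

#' Kullback-Leibler divergence of a diagonal Gaussian from the standard
#' normal
#'
#' `0.5 * sum(sigma^2 + mu^2 - 1 - log(sigma^2))` per sample, the
#' regularizer that keeps the learned feature distribution from collapsing.
#'
#' @param mu,sigma Matrices (samples x dims) or vectors of means and
#'   standard deviations.
#' @return Numeric vector of per-sample divergences (nats).
#' @export
kl_standard_normal <- function(mu, sigma) {
  if (is.null(dim(mu))) mu <- matrix(mu, 1)
  if (is.null(dim(sigma))) sigma <- matrix(sigma, 1)
  0.5 * rowSums(sigma^2 + mu^2 - 1 - 2 * log(sigma))
}
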