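#' Training hyperparameters
#'
#' @param lr Adam learning rate.
#' @param max_epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); the best-validation weights are restored.
#' @param val_fraction Fraction of the training set carved off (stratified)
#'   for validation-based early stopping.
#' @param min_epochs Minimum epochs before early stopping may trigger.
#' @param val_strategy `"segment"` (stratified by label) or `"subject"`
#'   (whole subjects held out, so early stopping tracks cross-subject
#'   generalization; used automatically by subject-wise cross-validation).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   weight matrices (biases and normalization parameters are exempt).
#' @param lr_decay Multiplicative learning-rate decay applied when the
#'   validation loss has not improved for `lr_patience` epochs (1 disables).
#' @param lr_patience Plateau length (epochs) before the decay fires.
#' @return A `train_hyper` list.
#' @export
train_hyper <- function(lr = 1e-3, max_epochs = 100, batch_size = 32,
                        patience = 5, val_fraction = 0.1, min_epochs = 2,
                        val_strategy = c("segment", "subject"),
                        weight_decay = 0, lr_decay = 0.5,
                        lr_patience = 2) {
  val_strategy <- match.arg(val_strategy)
  structure(list(lr = lr, max_epochs = max_epochs, batch_size = batch_size,
                 patience = patience, val_fraction = val_fraction,
                 min_epochs = min_epochs, val_strategy = val_strategy,
                 weight_decay = weight_decay, lr_decay = lr_decay,
                 lr_patience = lr_patience),
            class = "train_hyper")
}

# stratified index split: returns val indices
stratified_holdout <- function(labels, fraction, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val <- max(1L, round(length(idx) * fraction))
      val <- c(val, sample(idx, n_val))
    }
    sort(val)
  })
}

# hold out whole subjects covering ~fraction of the segments; falls back to
# the stratified split if that would leave a single-class training set
subject_holdout <- function(labels, subject_ids, fraction, seed) {
  val <- with_seed(seed, {
    subs <- sample(unique(subject_ids))
    take <- character(0)
    for (s in subs) {
      take <- c(take, s)
      if (mean(subject_ids %in% take) >= fraction) break
    }
    which(subject_ids %in% take)
  })
  ok <- length(unique(labels[-val])) == 2 && length(unique(labels[val])) >= 1
  if (!ok) return(stratified_holdout(labels, fraction, seed))
  sort(val)
}

#' Train a model on a segment set
#'
#' Minibatch Adam on cross-entropy (plus the KL regularizer for models with
#' a Gaussian embedding), with stratified validation-based early stopping.
#' Fully deterministic under a fixed seed.
#'
#' @param train_set A `segment_set` containing both classes.
#' @param config A `duformer_config`.
#' @param hyper A `train_hyper`.
#' @param model Architecture name (see [baseline_factory()]).
#' @param seed Integer seed controlling initialization, the validation
#'   split, minibatch order, reparameterization noise and dropout.
#' @param verbose Print per-epoch progress?
#' @return A `duformer_model`: list with `params`, `buffers`, `config`,
#'   `model_name`, `input_scale`, `history` (per-epoch losses) and `seed`.
#' @export
train_model <- function(train_set, config, hyper = train_hyper(),
                        model = "duformer", seed = 1L, verbose = FALSE) {
  stopifnot(inherits(train_set, "segment_set"))
  labels <- train_set$labels
  if (length(unique(labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  ms <- baseline_factory(model)
  config$seed <- as.integer(seed)
  x <- train_set$segments
  input_scale <- stats::sd(x)
  if (input_scale == 0) input_scale <- 1
  x <- x / input_scale

  n <- dim(x)[1]
  val_idx <- if ((hyper$val_strategy %||% "segment") == "subject") {
    subject_holdout(labels, train_set$subject_ids, hyper$val_fraction,
                    derive_seed(seed, "valsplit"))
  } else {
    stratified_holdout(labels, hyper$val_fraction,
                       derive_seed(seed, "valsplit"))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- x[tr_idx, , , drop = FALSE]
  y_tr <- labels[tr_idx]
  x_val <- x[val_idx, , , drop = FALSE]
  y_val <- labels[val_idx]

  # patch matrices depend only on the data: build them once and slice rows
  # per minibatch (skipped when they would not comfortably fit in memory)
  pc_tr <- NULL; pc_val <- NULL
  if (!is.null(ms$precompute)) {
    est <- as.double(n) * config$n_tokens_small *
      config$n_channels * config$temporal_kernel
    if (est < 1.5e8) {
      pc_tr <- ms$precompute(x_tr, config)
      pc_val <- ms$precompute(x_val, config)
    }
  }

  params <- ms$init(config)
  bufs <- ms$buffers(config)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, bufs = bufs, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  n_tr <- length(tr_idx)
  lam <- config$kl_weight
  reparam_on <- ms$has_reparam && isTRUE(config$use_reparam)
  lr_now <- hyper$lr
  stall <- 0L

  for (epoch in seq_len(hyper$max_epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("epoch", epoch)), sample(n_tr))
    set.seed(derive_seed(seed, paste0("noise", epoch)))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1, n_tr, by = hyper$batch_size)) {
      bi <- ord[start:min(start + hyper$batch_size - 1, n_tr)]
      if (length(bi) < 2) next  # batch statistics need >= 2 samples
      yb <- y_tr[bi]
      fw <- if (is.null(pc_tr)) {
        ms$forward(params, bufs, x_tr[bi, , , drop = FALSE], config, "train",
                   keep_cache = TRUE)
      } else {
        ms$forward(params, bufs, NULL, config, "train", keep_cache = TRUE,
                   precomp = pc_tr, batch_idx = bi)
      }
      bufs <- fw$buffers
      loss <- cross_entropy(fw$probs, yb)
      dlogits <- cross_entropy_grad(fw$probs, yb)
      dmu <- NULL; dsg <- NULL
      if (reparam_on && lam > 0) {
        loss <- loss + lam * mean(kl_standard_normal(fw$mu, fw$sigma))
        bsz <- length(bi)
        dmu <- lam * fw$mu / bsz
        dsg <- lam * (fw$sigma - 1 / fw$sigma) / bsz
      }
      grads <- ms$backward(dlogits, dmu, dsg, fw$cache, params, config)
      upd <- adam_step(params, grads, opt, lr = lr_now,
                       weight_decay = hyper$weight_decay %||% 0)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    vfw <- if (is.null(pc_val)) {
      ms$forward(params, bufs, x_val, config, "deterministic")
    } else {
      ms$forward(params, bufs, NULL, config, "deterministic",
                 precomp = pc_val, batch_idx = seq_along(y_val))
    }
    val_loss <- cross_entropy(vfw$probs, y_val)
    val_acc <- mean(max.col(vfw$probs) - 1L == y_val)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / max(1, n_batches),
                                   val_loss = val_loss, val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss / max(1, n_batches), val_loss, val_acc))
    }
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, bufs = bufs,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      lr_dec <- hyper$lr_decay %||% 1
      if (lr_dec < 1 && stall >= (hyper$lr_patience %||% 2)) {
        lr_now <- max(lr_now * lr_dec, 1e-4)
        stall <- 0L
      }
    }
    if (epoch >= hyper$min_epochs &&
        epoch - best$epoch >= hyper$patience) {
      break
    }
  }
  structure(
    list(params = best$params, buffers = best$bufs, config = config,
         model_name = model, input_scale = input_scale, history = hist,
         hyper = hyper, seed = as.integer(seed)),
    class = "duformer_model"
  )
}

#' @export
print.duformer_model <- function(x, ...) {
  cat(sprintf(
    "<duformer_model> %s: %d epochs trained (best val loss %.4f), embed %d\n",
    x$model_name, nrow(x$history), min(x$history$val_loss),
    x$config$embed_dim
  ))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param model A trained `duformer_model`.
#' @param x A `segment_set` or array (n, channels, samples).
#' @param mode `"deterministic"` (S = mu; the default for point
#'   predictions) or `"mc"` (one stochastic pass; seed the RNG first).
#' @param batch_size Internal batch size.
#' @return Matrix n x n_classes of probabilities.
#' @export
predict_proba <- function(model, x, mode = c("deterministic", "mc"),
                          batch_size = 128, precomp = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "segment_set")) x <- x$segments
  ms <- baseline_factory(model$model_name)
  x <- x / model$input_scale
  n <- dim(x)[1]
  out <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- if (is.null(precomp)) {
      ms$forward(model$params, model$buffers,
                 x[idx, , , drop = FALSE], model$config, mode)
    } else {
      ms$forward(model$params, model$buffers, NULL, model$config, mode,
                 precomp = precomp, batch_idx = idx)
    }
    out[idx, ] <- fw$probs
  }
  out
}

# patch precomputation for repeated prediction over the same data (used by
# Monte-Carlo uncertainty); returns NULL when unsupported or too large
prediction_precompute <- function(model, x) {
  ms <- baseline_factory(model$model_name)
  if (is.null(ms$precompute)) return(NULL)
  est <- as.double(dim(x)[1]) * model$config$n_tokens_small *
    model$config$n_channels * model$config$temporal_kernel
  if (est >= 1.5e8) return(NULL)
  ms$precompute(x / model$input_scale, model$config)
}

#' Classification metrics from labels, predictions and scores
#'
#' Accuracy, precision, recall, F1 (class 1 as positive) and rank-based
#' AUC (the probability that a random positive scores above a random
#' negative, ties counted half). AUC is `NA` when a class is absent.
#'
#' @param labels True labels in \{0, 1\}.
#' @param predicted Predicted labels in \{0, 1\}.
#' @param scores Numeric scores for class 1 (for AUC); optional.
#' @return Named list: accuracy, precision, recall, f1, auc.
#' @export
classification_metrics <- function(labels, predicted, scores = NULL) {
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fp <- sum(labels == 0 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auc <- NA_real_
  if (!is.null(scores) && length(unique(labels)) == 2) {
    r <- rank(scores)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, auc = auc)
}

#' Evaluate a trained model on a test segment set
#'
#' Deterministic predictions (S = mu).
#'
#' @param model A `duformer_model`.
#' @param test_set A `segment_set`.
#' @return Named list of metrics plus the confusion counts.
#' @export
evaluate_model <- function(model, test_set) {
  stopifnot(inherits(test_set, "segment_set"))
  if (dim(test_set$segments)[1] == 0) stop("empty test set", call. = FALSE)
  probs <- predict_proba(model, test_set)
  pred <- max.col(probs) - 1L
  m <- classification_metrics(test_set$labels, pred, probs[, 2])
  m$n <- length(pred)
  m
}

#' k-fold assignments for a segment set
#'
#' `"segment"` strategy stratifies folds by class label;
#' `"subject"` keeps all of a subject's segments in one fold (subjects are
#' balanced across folds), which avoids leakage between the overlapping
#' windows of one recording.
#'
#' @param segments A `segment_set`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param strategy `"segment"` or `"subject"`.
#' @return List of `k` integer vectors (test indices per fold), jointly a
#'   partition of the segment indices.
#' @export
kfold_split <- function(segments, k = 10, seed = 1L,
                        strategy = c("segment", "subject")) {
  strategy <- match.arg(strategy)
  labels <- segments$labels
  n <- length(labels)
  if (n < k) stop("need at least k segments", call. = FALSE)
  folds <- vector("list", k)
  with_seed(derive_seed(seed, paste0("kfold-", strategy)), {
    if (strategy == "segment") {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        assign_to <- rep_len(seq_len(k), length(idx))
        for (f in seq_len(k)) {
          folds[[f]] <- c(folds[[f]], idx[assign_to == f])
        }
      }
    } else {
      subs <- unique(segments$subject_ids)
      subs <- sample(subs)
      assign_to <- rep_len(seq_len(k), length(subs))
      for (f in seq_len(k)) {
        folds[[f]] <- which(segments$subject_ids %in% subs[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

subset_segments <- function(segments, idx) {
  segment_set(segments$segments[idx, , , drop = FALSE],
              segments$labels[idx], segments$subject_ids[idx],
              band = segments$band, sample_rate = segments$sample_rate)
}

#' k-fold cross-validation of one architecture on one segment set
#'
#' @param segments A `segment_set`.
#' @param config A `duformer_config`.
#' @param hyper A `train_hyper`.
#' @param k Folds (default 10).
#' @param seed Seed controlling fold assignment and per-fold training.
#' @param strategy Fold granularity, see [kfold_split()].
#' @param model Architecture name.
#' @return A `cv_report`: `folds` (per-fold metric data.frame), `mean`
#'   (metric means over folds), `assignments`, `config_hash`, `seed`.
#' @export
run_cv <- function(segments, config, hyper = train_hyper(), k = 10,
                   seed = 1L, strategy = c("segment", "subject"),
                   model = "duformer") {
  strategy <- match.arg(strategy)
  if (strategy == "subject") hyper$val_strategy <- "subject"
  folds <- kfold_split(segments, k, seed, strategy)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(length(segments$labels)), test_idx)
    fit <- train_model(subset_segments(segments, train_idx), config, hyper,
                       model = model, seed = derive_seed(seed, paste0("fold", f)))
    m <- evaluate_model(fit, subset_segments(segments, test_idx))
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, auc = m$auc, n_test = m$n)
  }
  folds_df <- do.call(rbind, rows)
  means <- colMeans(folds_df[, c("accuracy", "precision", "recall",
                                 "f1", "auc")], na.rm = TRUE)
  structure(
    list(folds = folds_df, mean = means, assignments = folds,
         model = model, strategy = strategy,
         config_hash = config_hash(config), seed = as.integer(seed)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds (%s strategy)\n",
              x$model, nrow(x$folds), x$strategy))
  print(round(x$mean, 4))
  invisible(x)
}

#' Per-band cross-validation experiment
#'
#' Runs [run_cv()] on each band's segment set and assembles the per-band
#' metric table (one row per band: mean accuracy, precision, recall, F1,
#' AUC over folds).
#'
#' @param band_sets Named list mapping band name to `segment_set`.
#' @param config,hyper,k,seed,strategy,model Passed to [run_cv()].
#' @return List: `table` (data.frame, one row per band), `reports` (the
#'   underlying `cv_report`s).
#' @export
run_band_experiment <- function(band_sets, config, hyper = train_hyper(),
                                k = 10, seed = 1L, strategy = "subject",
                                model = "duformer") {
  stopifnot(length(band_sets) >= 1)
  reports <- lapply(names(band_sets), function(b) {
    run_cv(band_sets[[b]], config, hyper, k, seed, strategy, model)
  })
  names(reports) <- names(band_sets)
  tab <- do.call(rbind, lapply(names(reports), function(b) {
    data.frame(band = b, t(reports[[b]]$mean))
  }))
  list(table = tab, reports = reports)
}

#' Ablation study: full model vs module-excluded variants
#'
#' Evaluates \{full, no SMHSA, no reparameterization\} under identical fold
#' assignments and seeds, quantifying each module's contribution.
#'
#' @param segments A `segment_set`.
#' @param config,hyper,k,seed,strategy Passed to [run_cv()].
#' @return List: `table` (one row per variant), `reports`.
#' @export
run_ablation <- function(segments, config, hyper = train_hyper(), k = 10,
                         seed = 1L, strategy = "subject") {
  variants <- list(
    full = config,
    no_smhsa = utils::modifyList(config, list(use_smhsa = FALSE)),
    no_reparam = utils::modifyList(config, list(use_reparam = FALSE))
  )
  for (v in names(variants)) class(variants[[v]]) <- class(config)
  reports <- lapply(variants, function(cf) {
    run_cv(segments, cf, hyper, k, seed, strategy, model = "duformer")
  })
  tab <- do.call(rbind, lapply(names(reports), function(v) {
    data.frame(variant = v, t(reports[[v]]$mean))
  }))
  list(table = tab, reports = reports)
}

#' Model comparison harness
#'
#' Cross-validates DU-former against the baseline architectures under
#' identical folds.
#'
#' @param segments A `segment_set`.
#' @param config,hyper,k,seed,strategy Passed to [run_cv()].
#' @param models Architectures to compare.
#' @return List: `table` (one row per model), `reports`.
#' @export
run_comparison <- function(segments, config, hyper = train_hyper(), k = 10,
                           seed = 1L, strategy = "subject",
                           models = c("duformer", "eegnet_like",
                                      "plain_transformer", "cnn")) {
  reports <- lapply(models, function(mn) {
    run_cv(segments, config, hyper, k, seed, strategy, model = mn)
  })
  names(reports) <- models
  tab <- do.call(rbind, lapply(models, function(mn) {
    data.frame(model = mn, t(reports[[mn]]$mean))
  }))
  list(table = tab, reports = reports)
}
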