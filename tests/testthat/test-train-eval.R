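make_toy_segments <- function(n = 60, n_subj = 12, seed = 4,
                              effect = 2.5, n_samples = 400) {
  set.seed(seed)
  x <- array(rnorm(n * 4 * n_samples), c(n, 4, n_samples))
  labels <- rep(c(0L, 1L), length.out = n)
  x[labels == 1, , ] <- x[labels == 1, , ] * sqrt(effect)
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), length.out = n)
  segment_set(x, labels, subj, sample_rate = 200)
}

test_that("kfold folds partition the data under both strategies", {
  segs <- make_toy_segments(n = 100, n_subj = 10)
  for (strat in c("segment", "subject")) {
    folds <- kfold_split(segs, 10, seed = 3, strategy = strat)
    expect_length(folds, 10)
    all_idx <- sort(unlist(folds))
    expect_identical(all_idx, seq_along(segs$labels))
    expect_equal(max(table(unlist(folds))), 1)  # pairwise disjoint
  }
  # segment strategy stratifies: ten folds of ten with balanced labels
  folds <- kfold_split(segs, 10, seed = 3, strategy = "segment")
  expect_true(all(lengths(folds) == 10))
  # subject strategy: no subject spans two folds
  folds_s <- kfold_split(segs, 5, seed = 3, strategy = "subject")
  for (f in folds_s) {
    subj_here <- unique(segs$subject_ids[f])
    others <- unlist(lapply(setdiff(seq_along(folds_s),
                                    which(vapply(folds_s, identical, TRUE,
                                                 f))),
                            function(i) segs$subject_ids[folds_s[[i]]]))
    expect_length(intersect(subj_here, unique(others)), 0)
  }
  expect_error(kfold_split(make_toy_segments(n = 5), 10), "at least k")
})

test_that("metrics match hand-computed confusion values", {
  m <- classification_metrics(labels = rep(1:0, c(4, 6)),
                              predicted = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  perfect <- classification_metrics(c(0, 1, 1), c(0, 1, 1), c(0.1, 0.9, 0.8))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "f1", "auc")]) == 1))

  # identical scores: AUC is 1/2 by rank symmetry
  tied <- classification_metrics(c(0, 1, 0, 1), c(0, 0, 0, 0),
                                 rep(0.4, 4))
  expect_equal(tied$auc, 0.5)

  # single-class labels: AUC reported missing, not 0
  onecls <- classification_metrics(c(1, 1), c(1, 0), c(0.9, 0.2))
  expect_true(is.na(onecls$auc))
})

test_that("rank AUC is invariant under monotone score transforms", {
  set.seed(8)
  labels <- rbinom(50, 1, 0.5)
  scores <- rnorm(50)
  a1 <- classification_metrics(labels, labels, scores)$auc
  a2 <- classification_metrics(labels, labels, exp(3 * scores) + 2)$auc
  expect_equal(a1, a2)
  skip_if_not_installed("pROC")
  a3 <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("training is deterministic and rejects single-class sets", {
  segs <- make_toy_segments()
  cfg <- tiny_config(seed = 1)
  hyp <- train_hyper(max_epochs = 3, patience = 3, batch_size = 16)
  f1 <- train_model(segs, cfg, hyp, seed = 7)
  f2 <- train_model(segs, cfg, hyp, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)

  bad <- subset_segments_for_test(segs, which(segs$labels == 1))
  expect_error(train_model(bad, cfg, hyp), "both classes")
})

test_that("a dominant KL weight drives the embedding to the prior", {
  segs <- make_toy_segments(n = 40, n_samples = 300)
  cfg_big <- tiny_config(kl_weight = 1000, seed = 1)
  cfg_zero <- tiny_config(kl_weight = 0, seed = 1)
  hyp <- train_hyper(max_epochs = 12, patience = 12, batch_size = 20,
                     lr_decay = 1)
  fit_big <- train_model(segs, cfg_big, hyp, seed = 2)
  fit_zero <- train_model(segs, cfg_zero, hyp, seed = 2)
  fw_big <- predict_embedding_for_test(fit_big, segs)
  fw_zero <- predict_embedding_for_test(fit_zero, segs)
  kl_big <- mean(kl_standard_normal(fw_big$mu, fw_big$sigma))
  kl_zero <- mean(kl_standard_normal(fw_zero$mu, fw_zero$sigma))
  expect_lt(kl_big, kl_zero)
})

test_that("every architecture learns a strongly separable toy problem", {
  segs <- make_toy_segments(n = 80, n_subj = 8, effect = 6, n_samples = 300)
  hyp <- train_hyper(max_epochs = 40, patience = 40, batch_size = 10,
                     lr = 3e-3, lr_decay = 1)
  for (mn in c("duformer", "cnn", "eegnet_like", "plain_transformer")) {
    cfg <- duformer_config(n_channels = 4, n_samples = 300, n_filters = 4,
                           temporal_kernel = 7, stride_large = 10,
                           stride_small = 5, embed_dim = 4, n_heads = 2,
                           ffn_expansion = 2, seed = 1)
    fit <- train_model(segs, cfg, hyp, model = mn, seed = 6)
    probs <- predict_proba(fit, segs)
    expect_equal(rowSums(probs), rep(1, 80), tolerance = 1e-6)
    acc <- mean((max.col(probs) - 1) == segs$labels)
    expect_gte(acc, 0.9)
  }
  expect_error(baseline_factory("mlp"), "unknown model")
})

test_that("mann-whitney U matches enumeration and the reference test", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, brute_force_mwu_p(c(1, 2, 3), c(4, 5, 6)))

  # symmetry: identical samples give U = n*m/2
  expect_equal(mann_whitney_u(1:4, 1:4)$u, 8)

  set.seed(21)
  for (r in 1:10) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(m, 0.5), 2)
    if (anyDuplicated(c(x, y))) next
    res <- mann_whitney_u(x, y)
    expect_equal(res$p_value, brute_force_mwu_p(x, y), tolerance = 1e-12)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$u, unname(ref$statistic))
  }

  # exact and normal approximation agree closely at n = m = 8
  set.seed(4)
  x <- rnorm(8); y <- rnorm(8, 1)
  exact_p <- mann_whitney_u(x, y)$p_value
  r <- rank(c(x, y))
  u <- sum(r[1:8]) - 8 * 9 / 2
  z <- (u - 32 - sign(u - 32) * 0.5) / sqrt(8 * 8 * 17 / 12)
  approx_p <- 2 * pnorm(-abs(z))
  expect_lt(abs(exact_p - approx_p), 0.01)

  # ties route to the corrected normal approximation
  res_t <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_equal(res_t$method, "normal_approx")
  ref_t <- suppressWarnings(wilcox.test(c(1, 2, 2), c(2, 3, 4),
                                        correct = TRUE))
  expect_equal(res_t$p_value, ref_t$p.value, tolerance = 1e-9)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})
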