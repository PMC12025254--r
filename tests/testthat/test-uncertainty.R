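fit_tiny_model <- function(effect = 4, seed = 10) {
  set.seed(seed)
  n <- 60
  x <- array(rnorm(n * 4 * 300), c(n, 4, 300))
  labels <- rep(c(0L, 1L), length.out = n)
  x[labels == 1, , ] <- x[labels == 1, , ] * sqrt(effect)
  segs <- segment_set(x, labels, rep(sprintf("S%02d", 1:6), length.out = n),
                      sample_rate = 150)
  cfg <- duformer_config(n_channels = 4, n_samples = 300, n_filters = 4,
                         temporal_kernel = 7, stride_large = 10,
                         stride_small = 5, embed_dim = 4, n_heads = 2,
                         ffn_expansion = 2, seed = 1)
  list(fit = train_model(segs, cfg, train_hyper(max_epochs = 15,
                                                patience = 15,
                                                batch_size = 20), seed = 2),
       segs = segs)
}

test_that("normalized predictive entropy hits its closed-form anchors", {
  u_of <- function(p) {
    h <- -sum(ifelse(p > 0, p * log(p), 0))
    h / log(length(p))
  }
  expect_equal(u_of(c(1, 0)), 0)
  expect_equal(u_of(c(0.5, 0.5)), 1)
  expect_equal(u_of(c(0.9, 0.1)), 0.469, tolerance = 1e-3)
})

test_that("mc_predict is seeded, bounded, and shape-stable", {
  tm <- fit_tiny_model()
  r1 <- mc_predict(tm$fit, tm$segs, K = 10, seed = 5)
  r2 <- mc_predict(tm$fit, tm$segs, K = 10, seed = 5)
  expect_identical(r1$samples, r2$samples)
  expect_true(all(r1$samples$uncertainty >= 0 &
                    r1$samples$uncertainty <= 1))
  expect_equal(r1$samples$p0 + r1$samples$p1, rep(1, 60), tolerance = 1e-9)
  expect_error(mc_predict(tm$fit, tm$segs, K = 0), "K must be")
})

test_that("histogram rates are normalized and bin correctly", {
  expect_error(uncertainty_histogram(numeric(0)), "empty")
  hh <- uncertainty_histogram(rep(0.05, 7))
  expect_equal(hh$rates[1], 1)
  expect_equal(sum(hh$rates), 1)
  set.seed(3)
  u <- runif(1e4)
  hh2 <- uncertainty_histogram(u)
  expect_equal(sum(hh2$rates), 1, tolerance = 1e-9)
  expect_true(all(abs(hh2$rates - 0.1) < 0.02))
})

test_that("acceptance rate is monotone in the threshold", {
  expect_equal(acceptance_rate(rep(0, 5)), 1)
  expect_equal(acceptance_rate(runif(50), threshold = 1), 1)
  set.seed(6)
  u <- runif(200)
  rates <- vapply(seq(0, 1, 0.1), function(th) acceptance_rate(u, th), 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("a model trained on separated classes is more certain on them", {
  # strong band-power effect vs a no-effect cohort from the same generator
  mk <- function(ratio) {
    preprocess_dataset(
      generate_dataset(synth_config(n_subjects = 10, duration_s = 5,
                                    effect_band = "Gamma",
                                    effect_ratio = ratio, seed = 17)),
      bands = eeg_bands()[7, , drop = FALSE]
    )$Gamma
  }
  segs <- mk(3)
  segs0 <- mk(1)
  mcfg <- duformer_config(n_filters = 16, embed_dim = 16,
                          stride_large = 20, stride_small = 20, seed = 1)
  fit <- train_model(segs, mcfg,
                     train_hyper(max_epochs = 12, patience = 4,
                                 batch_size = 16,
                                 val_strategy = "subject"), seed = 3)
  rep_sep <- mc_predict(fit, segs, K = 20, seed = 9)
  rep_null <- mc_predict(fit, segs0, K = 20, seed = 9)
  expect_gt(mean(rep_null$samples$uncertainty),
            mean(rep_sep$samples$uncertainty))
  expect_gt(acceptance_rate(rep_sep), acceptance_rate(rep_null))
})
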