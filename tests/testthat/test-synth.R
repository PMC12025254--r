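test_that("synth config validates its inputs", {
  expect_error(synth_config(effect_band = "Mu"), "unknown effect_band")
  expect_error(synth_config(effect_ratio = -1), "effect_ratio")
  expect_error(synth_config(duration_s = 1), "duration_s")
  expect_error(synth_config(oscillation_amplitudes = c(Delta = -1)),
               "amplitudes")
})

test_that("a pure tone lands in its band", {
  cfg <- synth_config(duration_s = 4,
                      oscillation_amplitudes = c(Delta = 0),
                      background_amplitude = 0,
                      tone_hz = 10, tone_amplitude = 2, seed = 1)
  rec <- generate_recording(cfg, "S01", "pre")
  frac <- band_power(rec, 8, 10.5) / band_power(rec, 0, 500)
  expect_true(all(frac >= 0.99))
})

test_that("generation is deterministic and class-paired", {
  cfg <- synth_config(n_subjects = 3, duration_s = 3, seed = 42)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1, ds2)
  expect_equal(length(ds1$recordings), 6)
  expect_equal(sum(ds1$manifest$class), 3)
  expect_error(generate_dataset(synth_config(n_subjects = 0, duration_s = 3)),
               "n_subjects")
})

test_that("effect ratio is expressed as the configured band-power ratio", {
  cfg <- synth_config(n_subjects = 25, duration_s = 4, effect_band = "Gamma",
                      effect_ratio = 2, seed = 7,
                      oscillation_amplitudes = c(Gamma = 1.5))
  p_post <- vapply(seq_len(25), function(i) {
    mean(band_power(generate_recording(cfg, sprintf("S%02d", i), "post"),
                    30, 50))
  }, 0)
  p_pre <- vapply(seq_len(25), function(i) {
    mean(band_power(generate_recording(cfg, sprintf("S%02d", i), "pre"),
                    30, 50))
  }, 0)
  expect_gt(mean(p_post) / mean(p_pre), 1.8)
  expect_lt(mean(p_post) / mean(p_pre), 2.2)
})

test_that("null effect gives calibrated two-sample tests", {
  # with effect_ratio = 1 the two class generators are identical in
  # distribution: p-values of a band-power t-test are uniform, so the
  # empirical type-I rate at alpha = 0.2 stays near nominal
  pvals <- vapply(1:40, function(r) {
    cfg <- synth_config(n_subjects = 6, duration_s = 3, effect_ratio = 1,
                        seed = 1000 + r,
                        oscillation_amplitudes = c(Gamma = 1.5))
    pre <- vapply(1:6, function(i) {
      mean(band_power(generate_recording(cfg, sprintf("S%02d", i), "pre"),
                      30, 50))
    }, 0)
    post <- vapply(1:6, function(i) {
      mean(band_power(generate_recording(cfg, sprintf("S%02d", i), "post"),
                      30, 50))
    }, 0)
    t.test(pre, post)$p.value
  }, 0)
  rate <- mean(pvals < 0.2)
  # binomial(40, 0.2) two-sided 99% range
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.45)
})

test_that("artifact injection returns faithful ground truth", {
  rec <- generate_recording(synth_config(n_subjects = 1, duration_s = 10,
                                         seed = 3), "S01", "pre")
  # zero amplitude is the identity
  ia0 <- inject_artifacts(rec, "ocular", seed = 1, amplitude = 0)
  expect_identical(ia0$recording$data, rec$data)

  ia <- inject_artifacts(rec, "ocular", seed = 5, rate = 12)
  expect_gt(cor(ia$recording$data[1, ], ia$reference), 0.8)  # Fp1 frontal
  expect_identical(ia$clean$data, rec$data)

  im <- inject_artifacts(rec, "myogenic", seed = 5, rate = 12)
  hf <- sum(band_power(im$component, 30, 500, 1000))
  tot <- sum(band_power(im$component, 0, 500, 1000))
  expect_gt(hf / tot, 0.5)

  expect_error(inject_artifacts(rec, "cardiac"), "arg")
})
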