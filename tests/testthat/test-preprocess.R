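make_clean_recording <- function(seed = 3, duration = 10) {
  generate_recording(synth_config(n_subjects = 1, duration_s = duration,
                                  seed = seed), "S01", "pre")
}

test_that("ocular removal needs a crossing component and improves RMSE", {
  rec <- make_clean_recording()
  ia <- inject_artifacts(rec, "ocular", seed = 5, rate = 12)
  res <- suppressWarnings(
    remove_ocular_artifacts(ia$recording, ia$reference, seed = 2)
  )
  expect_gte(sum(res$report$removed), 1)
  rmse_before <- sqrt(mean((ia$recording$data - ia$clean$data)^2))
  rmse_after <- sqrt(mean((res$recording$data - ia$clean$data)^2))
  expect_lt(rmse_after, rmse_before)
})

test_that("nothing is removed without a correlated component", {
  rec <- bandpass_filter(make_clean_recording())
  set.seed(9)
  res <- suppressWarnings(
    remove_ocular_artifacts(rec, rnorm(ncol(rec$data)), seed = 2)
  )
  expect_equal(sum(res$report$removed), 0)
  expect_lt(max(abs(res$recording$data - rec$data)), 1e-6)

  # an unattainable threshold removes nothing even with real artifacts
  ia <- inject_artifacts(rec, "ocular", seed = 5, rate = 12)
  res1 <- suppressWarnings(
    remove_ocular_artifacts(ia$recording, ia$reference, r_threshold = 1,
                            seed = 2)
  )
  expect_equal(sum(res1$report$removed), 0)
})

test_that("myogenic suppression reduces high-frequency power", {
  rec <- make_clean_recording(seed = 7, duration = 20)
  im <- inject_artifacts(rec, "myogenic", seed = 5, rate = 20)
  recf <- bandpass_filter(im$recording)
  res <- suppressWarnings(suppress_myogenic_artifacts(recf, seed = 2))
  expect_gte(sum(res$report$removed), 1)
  hf_before <- sum(band_power(recf, 30, 50))
  hf_after <- sum(band_power(res$recording, 30, 50, 1000))
  expect_lt(hf_after, hf_before)

  # threshold 1 is identity behavior (up to reconstruction error)
  res1 <- suppressWarnings(
    suppress_myogenic_artifacts(recf, hf_power_fraction_threshold = 1,
                                seed = 2)
  )
  expect_equal(sum(res1$report$removed), 0)
  expect_lt(max(abs(res1$recording$data - recf$data)), 1e-6)
})

test_that("artifact removal never alters the data dimensions", {
  rec <- bandpass_filter(make_clean_recording(seed = 11, duration = 6))
  set.seed(1)
  res <- suppressWarnings(
    remove_ocular_artifacts(rec, rnorm(ncol(rec$data)), seed = 3)
  )
  expect_identical(dim(res$recording$data), dim(rec$data))
  res2 <- suppressWarnings(suppress_myogenic_artifacts(rec, seed = 3))
  expect_identical(dim(res2$recording$data), dim(rec$data))
})

test_that("spherical spline interpolation reconstructs smooth fields", {
  mont <- eeg_montage()
  rec <- make_clean_recording(seed = 5, duration = 2)

  # no bad channels: identity
  expect_identical(interpolate_bad_channels(rec, character(0)), rec)

  # spatially constant signal is reproduced exactly for any bad channel
  const <- eeg_recording(matrix(5, 16, 200), mont$label, 1000)
  out <- interpolate_bad_channels(const, "Pz")
  expect_equal(out$data[which(mont$label == "Pz"), ],
               rep(5, 200), tolerance = 0.01)

  # smooth spatial field: spline beats nearest-neighbour substitution
  field <- as.matrix(mont[, c("x", "y", "z")]) %*% c(1, 2, 3)
  sig <- outer(as.numeric(field), sin(2 * pi * 5 * (1:500) / 1000))
  recs <- eeg_recording(sig, mont$label, 1000)
  for (ch in c("C3", "Fz", "O1")) {
    i <- which(mont$label == ch)
    est <- interpolate_bad_channels(recs, ch)$data[i, ]
    d <- as.matrix(dist(mont[, c("x", "y", "z")]))
    diag(d) <- Inf
    nn <- which.min(d[i, ])
    err_spline <- sqrt(mean((est - sig[i, ])^2))
    err_nn <- sqrt(mean((sig[nn, ] - sig[i, ])^2))
    expect_lt(err_spline, err_nn)
  }

  expect_error(interpolate_bad_channels(rec, mont$label[1:13]),
               "at least 4 good channels")
})

test_that("segmentation obeys the count formula", {
  # grid over (T, W, S)
  for (n in c(2000, 2500, 9999, 10000)) {
    for (w in c(1000, 2000)) {
      for (s in c(500, 1000, 1500)) {
        expect_identical(n_segments(n, w, s),
                         as.integer(floor((n - w) / s) + 1))
      }
    }
  }
  expect_identical(n_segments(1999, 2000, 1000), 0L)

  rec <- make_clean_recording(seed = 2, duration = 10)
  ss <- segment_recording(rec)  # 2 s window, 1 s step at 1000 Hz
  expect_equal(dim(ss$segments), c(9, 16, 2000))
  expect_true(all(ss$labels == 0))
  expect_true(all(ss$subject_ids == "S01"))
  # consecutive segments overlap by window - step samples
  expect_identical(ss$segments[1, , 1001:2000], ss$segments[2, , 1:1000])

  one <- update_data(rec, rec$data[, 1:2000])
  expect_equal(dim(segment_recording(one)$segments)[1], 1)
  short <- update_data(rec, rec$data[, 1:1999])
  expect_warning(empty <- segment_recording(short), "shorter")
  expect_equal(dim(empty$segments)[1], 0)
})

test_that("the pipeline composes, logs provenance, and is deterministic", {
  rec <- make_clean_recording(seed = 4, duration = 8)
  out1 <- preprocess_pipeline(rec, bands = eeg_bands()[c(1, 7), ])
  out2 <- preprocess_pipeline(rec, bands = eeg_bands()[c(1, 7), ])
  expect_identical(out1$bands, out2$bands)
  expect_named(out1$bands, c("Delta", "Gamma"))
  counts <- vapply(out1$bands, function(s) dim(s$segments)[1], 0)
  expect_true(all(counts == 7))  # floor((8000-2000)/1000)+1
  expect_true("bandpass_filter" %in% out1$provenance$stage)

  # toggling artifact stages changes only those stages
  ia <- inject_artifacts(rec, "ocular", seed = 6, rate = 12)
  with_art <- suppressWarnings(
    preprocess_pipeline(ia$recording, bands = eeg_bands()[7, , drop = FALSE],
                        reference_trace = ia$reference)
  )
  without <- preprocess_pipeline(ia$recording,
                                 bands = eeg_bands()[7, , drop = FALSE])
  expect_true("remove_ocular_artifacts" %in% with_art$provenance$stage)
  expect_false("remove_ocular_artifacts" %in% without$provenance$stage)
  expect_false(identical(with_art$bands$Gamma$segments,
                         without$bands$Gamma$segments))
})
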