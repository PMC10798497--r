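test_that("synthetic features are band-limited, z-scored, weakly correlated", {
  spec <- synth_spec(n_pieces = 3, duration_s = 60, seed = 5)
  fms <- gen_features(spec)
  expect_length(fms, 3)
  for (fm in fms) {
    expect_s3_class(fm, "feature_matrix")
    expect_identical(colnames(fm$data), canonical_features())
    expect_equal(fm$rate, 10)
    expect_equal(unname(colMeans(fm$data)), rep(0, 6), tolerance = 1e-9)
    expect_equal(unname(apply(fm$data, 2, pop_sd)), rep(1, 6),
                 tolerance = 1e-9)
    # pairwise correlation bound enforced by the generator
    expect_lt(max(abs(stats::cor(fm$data)[upper.tri(diag(6))])), 0.7)
    # band limit: energy above 0.5 Hz is negligible
    v <- fm$data[, "loudness"]
    sp <- abs(stats::fft(v))^2
    f <- (seq_along(v) - 1) / length(v) * 10
    f <- pmin(f, 10 - f)
    expect_lt(sum(sp[f > 0.55]) / sum(sp), 1e-6)
  }
  # reproducibility and piece-to-piece variation
  fms2 <- gen_features(spec)
  expect_identical(fms[[2]]$data, fms2[[2]]$data)
  expect_false(identical(fms[[1]]$data, fms[[2]]$data))
})

test_that("the tension target is the forward model plus calibrated noise", {
  spec <- synth_spec(n_pieces = 1, duration_s = 60, seed = 6)
  fm <- gen_features(spec)[[1]]
  p <- spec$true_params

  noiseless <- gen_tension(fm, p, noise_sd = 0, seed = 1, forward_lag_s = 0)
  pred <- predict_tension(fm, p)
  expect_equal(noiseless$values, zstandardize(pred$values),
               tolerance = 1e-12)
  expect_equal(noiseless$t0, pred$t0)

  # forward lag moves the trace later without touching the values
  lagged <- gen_tension(fm, p, noise_sd = 0, seed = 1, forward_lag_s = 4.5)
  expect_equal(lagged$t0, pred$t0 + 4.5)
  expect_equal(lagged$values, noiseless$values, tolerance = 1e-12)

  # noise level: correlation with the noiseless trace matches 1/sqrt(1+s^2)
  noisy <- gen_tension(fm, p, noise_sd = 0.2, seed = 2, forward_lag_s = 0)
  expect_equal(stats::cor(noisy$values, noiseless$values),
               1 / sqrt(1 + 0.04), tolerance = 0.05)
  expect_equal(mean(noisy$values), 0, tolerance = 1e-9)
  expect_equal(pop_sd(noisy$values), 1, tolerance = 1e-9)
})

test_that("simulated raters start at 0.30, track tension, and never go negative", {
  spec <- synth_spec(n_pieces = 1, duration_s = 60, seed = 7)
  fm <- gen_features(spec)[[1]]
  truth <- gen_tension(fm, spec$true_params, noise_sd = 0, seed = 3,
                       forward_lag_s = 0)
  rs <- gen_raters(truth, rater_count = 24, seed = 4)
  expect_s3_class(rs, "rating_set")
  expect_equal(nrow(rs$raters), 24)
  expect_equal(rs$rate, 60)
  expect_equal(unname(rs$raters[, 1]), rep(0.30, 24))
  expect_true(all(rs$raters >= 0))
  # nominal peak near 70% of the slider scale (gain jitter spreads it)
  expect_equal(mean(apply(rs$raters, 1, max)), 0.70, tolerance = 0.1)

  # the z-scored mean trace recovers the lagged truth
  mt <- resample_series(rs$mean_trace, 2)
  tr <- resample_series(truth, 2)
  sp <- lagged_spearman(tr, mt, lag_s = 4.5)
  expect_gt(sp$rho, 0.9)
})

test_that("corpus generation wires targets for both study designs", {
  spec <- synth_spec(n_pieces = 2, duration_s = 45, seed = 8)
  ct <- gen_corpus(spec, target = "trace")
  expect_length(ct, 2)
  expect_s3_class(ct[[1]]$ratings, "feature_series")
  # trace target is forward-lagged relative to the features
  expect_gt(ct[[1]]$ratings$t0, ct[[1]]$features$t0)

  cr <- gen_corpus(spec, target = "raters")
  expect_s3_class(cr[[1]]$ratings, "rating_set")
  expect_equal(nrow(cr[[1]]$ratings$raters), spec$rater_count)

  # determinism across calls
  ct2 <- gen_corpus(spec, target = "trace")
  expect_identical(ct[[2]]$ratings$values, ct2[[2]]$ratings$values)
})

test_that("audio fixtures are deterministic, bounded, and carry truth", {
  ga1 <- gen_audio("click_train", list(rate_per_min = 120), seed = 5)
  ga2 <- gen_audio("click_train", list(rate_per_min = 120), seed = 5)
  expect_identical(ga1$audio$samples, ga2$audio$samples)
  expect_true(all(abs(ga1$audio$samples) <= 1))
  expect_equal(ga1$truth$tempo_bpm, 120)
  expect_true(all(diff(ga1$truth$onset_times_s) > 0))

  ga3 <- gen_audio("sine", list(freq = 220))
  expect_equal(ga3$truth$midi, 57)
})

test_that("a corpus round-trips through the CSV layout on disk", {
  spec <- synth_spec(n_pieces = 2, duration_s = 30, seed = 9,
                     rater_count = 3)
  dir <- file.path(tempdir(), "corpus_rt")
  write_corpus(spec, dir, target = "raters")
  back <- read_corpus(dir)
  orig <- gen_corpus(spec, target = "raters")
  expect_length(back, 2)
  expect_equal(back[[1]]$features$data, orig[[1]]$features$data,
               tolerance = 1e-9)
  expect_equal(back[[2]]$ratings$raters, orig[[2]]$ratings$raters,
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
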