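test_that("loudness is monotone in signal level and postprocessing z-scores", {
  clips <- lapply(c(0.05, 0.1, 0.2, 0.4), function(a)
    gen_audio("sine", list(amp = a, duration_s = 3), seed = 1)$audio)
  raw_means <- vapply(clips, function(cl)
    mean(extract_loudness(cl, raw = TRUE)$values), numeric(1))
  expect_true(all(diff(raw_means) > 0))

  # doubling amplitude adds ~6 dB SPL -> sone ratio 2^(6/10)
  expect_equal(raw_means[2] / raw_means[1], 2^(6 / 10), tolerance = 0.05)

  z <- extract_loudness(gen_audio("ramped_noise", seed = 2)$audio)
  expect_s3_class(z, "feature_series")
  expect_equal(z$rate, 10)
  expect_equal(mean(z$values), 0, tolerance = 1e-9)
  expect_equal(pop_sd(z$values), 1, tolerance = 1e-9)
})

test_that("roughness separates pure tones from amplitude-modulated tones", {
  pure <- gen_audio("sine", list(freq = 1000, duration_s = 4))$audio
  am70 <- gen_audio("am_tone", list(freq = 1000, mod_freq = 70,
                                    duration_s = 4))$audio
  am10 <- gen_audio("am_tone", list(freq = 1000, mod_freq = 10,
                                    duration_s = 4))$audio
  r_pure <- mean(extract_roughness(pure, raw = TRUE)$values)
  r_am70 <- mean(extract_roughness(am70, raw = TRUE)$values)
  r_am10 <- mean(extract_roughness(am10, raw = TRUE)$values)
  expect_gt(r_am70, 10 * max(r_pure, 1e-12))
  # 70 Hz modulation sits at the roughness-weighting peak; 10 Hz is below band
  expect_gt(r_am70, r_am10)
})

test_that("onset detection recovers a click train within 50 ms", {
  ga <- gen_audio("click_train", list(rate_per_min = 120, duration_s = 10),
                  seed = 3)
  det <- detect_onsets(ga$audio)
  expect_s3_class(det, "onset_list")
  truth <- ga$truth$onset_times_s
  hits <- vapply(truth, function(o)
    any(abs(det$onset_times_s - o) <= 0.05), logical(1))
  expect_gte(mean(hits), 0.9)
  # no more than one spurious onset per two true ones
  expect_lte(length(det$onset_times_s), 1.5 * length(truth))
})

test_that("onset-frequency step series follows inter-onset spacing", {
  # constructed onset list: dense first half, sparse second half
  on <- c(seq(0.5, 4.5, by = 0.25), seq(5.5, 9.5, by = 1))
  t_grid <- seq(0, 10 - 1e-9, by = 0.1)
  v <- tensiontrend:::.onset_step_values(on, t_grid, 0, 10)$values
  expect_equal(length(v), 100)
  # larger inter-onset gaps in the second half -> lower values there
  expect_gt(mean(v[10:45]), mean(v[60:95]))

  ga <- gen_audio("click_train", list(rate_per_min = 150, duration_s = 8))
  fs <- extract_onset_frequency(ga$audio)
  expect_equal(fs$rate, 10)
  expect_equal(length(fs$values), 80)
})

test_that("tempo estimation finds the click-train rate in the folded range", {
  for (rpm in c(100, 120, 160)) {
    ga <- gen_audio("click_train", list(rate_per_min = rpm,
                                        duration_s = 12), seed = rpm)
    fs <- extract_tempo(ga$audio, raw = TRUE)
    expect_equal(stats::median(fs$values), rpm, tolerance = 0.05,
                 label = sprintf("tempo at %d bpm", rpm))
    expect_true(all(fs$values >= 90 - 1e-9 & fs$values < 180 + 1e-9))
  }
  # octave folding: 60 bpm clicks should read as 120
  ga <- gen_audio("click_train", list(rate_per_min = 60, duration_s = 16))
  fs <- extract_tempo(ga$audio, raw = TRUE)
  expect_equal(stats::median(fs$values), 120, tolerance = 0.05)
})

test_that("pitch tracking recovers pure-tone and chord mean pitch height", {
  s440 <- gen_audio("sine", list(freq = 440, duration_s = 3))$audio
  fs <- extract_pitch(s440, raw = TRUE)
  expect_equal(stats::median(fs$values), 69, tolerance = 0.5)

  s220 <- gen_audio("sine", list(freq = 220, duration_s = 3))$audio
  expect_equal(stats::median(extract_pitch(s220, raw = TRUE)$values), 57,
               tolerance = 0.5)

  # two simultaneous notes an octave apart -> mean near the midpoint
  ch <- gen_audio("chord_sequence",
                  list(chords = list(c(60, 72)), chord_dur_s = 3))$audio
  fs <- extract_pitch(ch, raw = TRUE)
  expect_equal(stats::median(fs$values), 66, tolerance = 1)
})

test_that("extract_all returns the canonical aligned feature matrix", {
  ga <- gen_audio("chord_sequence",
                  list(chords = list(c(60, 64, 67), c(62, 65, 69),
                                     c(64, 67, 71), c(60, 64, 67)),
                       chord_dur_s = 2))
  fm <- extract_all(ga$audio)
  expect_s3_class(fm, "feature_matrix")
  expect_identical(colnames(fm$data), canonical_features())
  expect_equal(fm$rate, 10)
  # all columns postprocessed to z-scores on a common length
  expect_true(all(abs(colMeans(fm$data)) < 1e-9))
})
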