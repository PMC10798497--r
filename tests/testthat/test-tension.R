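test_that("attentional slopes recover exact and closed-form OLS slopes", {
  # constant feature -> all slopes 0
  fs <- fs_from_fun(function(t) rep(1.3, length(t)), 20)
  sl <- attentional_slopes(fs, window_spec(3, 0))
  expect_true(all(abs(sl$raw) < 1e-12))

  # exact line: every slope equals the line's slope to machine precision
  fs <- fs_from_fun(function(t) 2 * t, 20)
  sl <- attentional_slopes(fs, window_spec(3, 0))
  expect_equal(sl$raw, rep(2, length(sl$raw)), tolerance = 1e-12)

  # seeded noisy ramp vs the direct per-window formula
  set.seed(21)
  fs <- fs_from_fun(function(t) 0.3 * t + rnorm(length(t), sd = 0.5), 30)
  sl <- attentional_slopes(fs, window_spec(4, 0))
  oracle <- vapply(sl$times_s, function(te) ols_slope_oracle(fs, te, 4),
                   numeric(1))
  expect_equal(sl$raw, oracle, tolerance = 1e-10)

  # windows are timestamped at their end and step by step_s
  expect_equal(sl$times_s[1], 4)
  expect_equal(unique(round(diff(sl$times_s), 10)), 0.25)

  expect_error(attentional_slopes(fs_from_fun(function(t) t, 2),
                                  window_spec(5, 0)), "does not fit")
})

test_that("memory gating amplifies only matching nonzero trend directions", {
  beta <- 5
  for (s_mem in c(-0.1, 0, 0.1)) {
    for (s_att in c(-0.4, 0, 0.4)) {
      fs <- fs_two_slopes(s_mem, s_att, d = 3, m = 3)
      sl <- memory_gate(attentional_slopes(fs, window_spec(3, 3)), fs,
                        beta = beta)
      i <- which(abs(sl$times_s - 6) < 1e-9)   # window pair ending at d + m
      match_sign <- s_mem != 0 && s_att != 0 && sign(s_mem) == sign(s_att)
      expected <- if (match_sign) beta * s_att else s_att
      expect_equal(sl$gated[i], expected, tolerance = 1e-9,
                   label = sprintf("mem %g, att %g", s_mem, s_att))
    }
  }
})

test_that("gating is inactive without a memory window or before its span", {
  set.seed(2)
  fs <- fs_from_fun(function(t) cumsum(rnorm(length(t), sd = 0.1)), 30)
  sl0 <- memory_gate(attentional_slopes(fs, window_spec(3, 0)), fs)
  expect_identical(sl0$gated, sl0$raw)

  sl <- memory_gate(attentional_slopes(fs, window_spec(3, 3)), fs)
  early <- sl$times_s < 6 - 1e-9
  expect_identical(sl$gated[early], sl$raw[early])
  # gated magnitudes are either raw or beta * raw
  ratio <- abs(sl$gated / sl$raw)
  ratio <- ratio[is.finite(ratio)]
  expect_true(all(abs(ratio - 1) < 1e-9 | abs(ratio - 5) < 1e-9))
})

test_that("slope integration has uniform-mean and fixed-point limits", {
  set.seed(13)
  fs <- fs_from_fun(function(t) cumsum(rnorm(length(t), sd = 0.1)), 30)
  sl <- memory_gate(attentional_slopes(fs, window_spec(3, 0)), fs)

  # lambda = 1: plain mean of the last 12 gated slopes
  int1 <- integrate_slopes(sl, integration_window_s = 3, decay = 1)
  g <- sl$gated
  n <- length(g)
  expect_equal(int1$integrated[n], mean(g[(n - 11):n]), tolerance = 1e-12)
  expect_equal(int1$integrated[20], mean(g[9:20]), tolerance = 1e-12)

  # constant gated slope is a fixed point for any lambda
  slc <- sl; slc$gated <- rep(0.37, n)
  for (lam in c(0.5, 0.8, 1)) {
    intc <- integrate_slopes(slc, decay = lam)
    expect_equal(intc$integrated, rep(0.37, n), tolerance = 1e-12)
  }

  # seeded sequence vs direct weighted-sum loop, lambda = 0.8
  int8 <- integrate_slopes(sl, decay = 0.8)
  w <- 0.8^(0:11)
  for (i in c(1, 5, 12, 30, n)) {
    avail <- min(12, i)
    wi <- w[seq_len(avail)]
    expect_equal(int8$integrated[i],
                 sum(g[i - seq_len(avail) + 1] * wi) / sum(wi),
                 tolerance = 1e-12)
  }
})

test_that("tension prediction is the weighted sum of integrated trends", {
  corpus <- small_corpus(n_pieces = 1, duration_s = 40, seed = 4)
  fm <- corpus[[1]]$features
  base <- default_true_params("weighted")

  zero_w <- base
  zero_w$weights[] <- 0
  expect_true(all(predict_tension(fm, zero_w)$values == 0))

  # projection: a single unit weight returns that feature's own trend
  proj <- base; proj$weights[] <- 0; proj$weights["pitch"] <- 1
  pt <- predict_tension(fm, proj)
  man <- integrate_slopes(
    memory_gate(attentional_slopes(get_feature(fm, "pitch"),
                                   base$windows), get_feature(fm, "pitch"),
                beta = base$beta),
    base$integration_window_s, base$decay)
  keep <- man$times_s >= 6 - 1e-9
  expect_equal(pt$values, man$integrated[keep], tolerance = 1e-12)

  # additivity / linearity in the weights
  w1 <- base; w1$weights[] <- 0; w1$weights["loudness"] <- 0.8
  w2 <- base; w2$weights[] <- 0; w2$weights["tempo"] <- -0.3
  w12 <- base; w12$weights[] <- 0
  w12$weights[c("loudness", "tempo")] <- c(0.8, -0.3)
  expect_equal(predict_tension(fm, w12)$values,
               predict_tension(fm, w1)$values +
                 predict_tension(fm, w2)$values,
               tolerance = 1e-12)

  # error names the missing feature
  fm5 <- feature_matrix(fm$data[, colnames(fm$data) != "tempo"],
                        fm$rate, piece_id = fm$piece_id)
  expect_error(predict_tension(fm5, base), "tempo")
})

test_that("prediction is causal and monotone in the amplification gain", {
  corpus <- small_corpus(n_pieces = 1, duration_s = 40, seed = 6)
  fm <- corpus[[1]]$features
  params <- default_true_params("weighted")
  pt <- predict_tension(fm, params)

  # causality: perturbing the future leaves earlier predictions unchanged
  fm2 <- fm
  cut <- round(30 * fm$rate)
  fm2$data[cut:nrow(fm2$data), ] <- 0
  pt2 <- predict_tension(fm2, params)
  tt <- series_times(pt)
  early <- tt < 29
  expect_equal(pt$values[early], pt2$values[early], tolerance = 1e-12)

  # beta-monotonicity on an always-rising feature (matching signs)
  fs <- fs_from_fun(function(t) 0.5 * t, 30)
  mag <- vapply(c(1, 2, 5, 8), function(b) {
    sl <- integrate_slopes(memory_gate(
      attentional_slopes(fs, window_spec(3, 3)), fs, beta = b))
    mean(abs(sl$integrated[sl$times_s >= 6]))
  }, numeric(1))
  expect_true(all(diff(mag) >= -1e-12))
})

test_that("model parameters round-trip through JSON", {
  p <- default_true_params("timescale")
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  q <- read_params_json(f)
  expect_equal(q$weights, p$weights)
  expect_equal(q$variant, p$variant)
  expect_equal(q$windows$pitch$memory_s, p$windows$pitch$memory_s)
  expect_equal(q$decay, p$decay)
  unlink(f)
})
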