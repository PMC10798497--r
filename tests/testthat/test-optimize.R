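test_that("design columns are the integrated trends on the design lattice", {
  corpus <- small_corpus(n_pieces = 2, duration_s = 50, seed = 8)
  grid <- data.frame(d = 3, m = 3)
  design <- build_design(corpus, grid)
  expect_s3_class(design, "slope_design")
  expect_identical(colnames(design$X),
                   sprintf("%s_d3_m3", canonical_features()))
  expect_equal(length(design$y), nrow(design$X))
  expect_equal(length(unique(design$piece)), 2)

  # oracle: single-feature projection of the forward model, block-meaned
  pz <- corpus[[1]]
  p <- default_true_params("weighted")   # windows (3, 3)
  proj <- p; proj$weights[] <- 0; proj$weights["roughness"] <- 1
  trend <- resample_series(predict_tension(pz$features, proj), 2)
  rows <- design$piece == pz$features$piece_id
  col <- design$X[rows, "roughness_d3_m3"]
  # the design drops rows where the 4.5 s-ahead target is unavailable, so
  # compare on the leading overlap
  expect_equal(col, trend$values[seq_along(col)], tolerance = 1e-10)

  # target alignment: y at a row stamped t is the rating trace at t + 4.5
  target <- resample_series(pz$ratings, 2)
  t_row <- trend$times_s <- series_times(trend)[seq_along(col)]
  ti <- round((t_row + 4.5 - target$t0) * 2) + 1
  expect_equal(design$y[rows], target$values[ti], tolerance = 1e-12)
})

test_that("piece-wise centering removes per-piece means exactly", {
  set.seed(15)
  piece <- rep(c("a", "b", "c"), times = c(10, 20, 15))
  M <- cbind(rnorm(45), rnorm(45, 3))
  Mc <- tensiontrend:::.center_by_piece(M, piece)
  for (p in unique(piece)) {
    expect_equal(colMeans(Mc[piece == p, , drop = FALSE]), c(0, 0),
                 tolerance = 1e-12)
  }
  # matches the lm-on-piece-dummies residual oracle
  r <- stats::residuals(stats::lm(M[, 1] ~ 0 + factor(piece)))
  expect_equal(unname(Mc[, 1]), unname(r), tolerance = 1e-12)
})

test_that("weight fitting matches the fixed-intercept least-squares oracle", {
  set.seed(23)
  n_per <- 80
  pieces <- rep(c("p1", "p2", "p3"), each = n_per)
  X <- matrix(rnorm(3 * n_per * 6), ncol = 6)
  colnames(X) <- canonical_features()
  w_true <- c(1, 0.5, -0.2, 0.2, 0.5, 0.5)
  ints <- c(p1 = -1, p2 = 0.5, p3 = 2)
  y <- as.numeric(X %*% w_true) + ints[pieces] + rnorm(length(pieces), sd = 0.1)
  design <- structure(list(X = X, y = y, piece = pieces,
                           columns = data.frame(
                             feature = canonical_features(), d = 3, m = 3),
                           design_rate = 2, lag_s = 4.5),
                      class = "slope_design")
  fit <- fit_weights(design)
  oracle <- stats::coef(stats::lm(y ~ 0 + factor(pieces) + X))
  expect_equal(unname(fit$weights), unname(oracle[4:9]), tolerance = 1e-10)
  expect_equal(unname(fit$weights), w_true, tolerance = 0.05)
  expect_equal(unname(fit$piece_intercepts[c("p1", "p2", "p3")]),
               unname(ints), tolerance = 0.05)
  expect_gt(fit$marginal_r2, 0.3)
  expect_lt(fit$marginal_r2, 1)

  # duplicated column is reported by name
  bad <- design
  bad$X[, "tempo"] <- bad$X[, "pitch"]
  expect_error(fit_weights(bad), "collinear")
})

test_that("grouped selection recovers the generating window pair", {
  corpus <- small_corpus(n_pieces = 4, duration_s = 60, seed = 11,
                         noise_sd = 0.1)
  design <- build_design(corpus, window_grid("weighted"))
  sel <- select_windows_grouped(design)
  expect_equal(sel$window$attentional_s, 3)
  expect_equal(sel$window$memory_s, 3)
  expect_false(sel$weak)
  expect_gt(sel$r2, 0.05)

  # a shuffled target carries no trend signal: the fit must be flagged weak
  shuffled <- design
  set.seed(99)
  shuffled$y <- sample(shuffled$y)
  sel0 <- select_windows_grouped(shuffled)
  expect_true(sel0$weak)
})

test_that("weighted optimization recovers weights up to scale", {
  corpus <- small_corpus(n_pieces = 4, duration_s = 60, seed = 11,
                         noise_sd = 0.1)
  fit <- optimize_model(corpus, "weighted")
  expect_s3_class(fit, "fit_result")
  expect_equal(fit$selected_windows$attentional_s, 3)
  expect_equal(fit$selected_windows$memory_s, 3)

  w_true <- default_true_params("weighted")$weights
  u_true <- w_true / sqrt(sum(w_true^2))
  u_hat <- fit$weights / sqrt(sum(fit$weights^2))
  expect_equal(unname(u_hat), unname(u_true[names(fit$weights)]),
               tolerance = 0.15)

  # the returned params drive the predictor directly
  pred <- predict_tension(corpus[[1]]$features, fit$params)
  expect_s3_class(pred, "tension_series")
  expect_gt(length(pred$values), 100)
})

test_that("per-feature selection assigns one window pair per feature", {
  corpus <- small_corpus(n_pieces = 4, duration_s = 60, seed = 12,
                         variant = "timescale", noise_sd = 0.1)
  # a reduced candidate grid keeps the unit test fast; the full grid is
  # exercised in the acceptance suite
  grid <- expand.grid(d = c(3, 5, 7), m = c(3, 4, 12))
  design <- build_design(corpus, grid)
  sel <- select_windows_per_feature(design)
  expect_identical(names(sel$windows), canonical_features())
  for (f in canonical_features()) {
    expect_s3_class(sel$windows[[f]], "window_spec")
    expect_true(sel$windows[[f]]$attentional_s %in% c(3, 5, 7))
    expect_true(sel$windows[[f]]$memory_s %in% c(3, 4, 12))
  }
  # truth for loudness/roughness/pitch/tonal lies inside this grid
  truth <- default_true_params("timescale")$windows
  hits <- vapply(c("loudness", "roughness", "pitch", "tonal_tension"),
                 function(f)
                   sel$windows[[f]]$attentional_s ==
                     truth[[f]]$attentional_s &&
                   sel$windows[[f]]$memory_s == truth[[f]]$memory_s,
                 logical(1))
  expect_gte(sum(hits), 2)
})
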