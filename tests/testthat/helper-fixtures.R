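# Shared fixture builders for the test suite.

# feature series from a function of time, sampled at `rate` over `dur_s`
fs_from_fun <- function(f, dur_s, rate = 10, name = "loudness",
                        piece = "p") {
  t <- seq(0, dur_s, by = 1 / rate)
  feature_series(f(t), rate, piece_id = piece, feature_name = name)
}

# piecewise-linear feature with slope `s_mem` over [0, m] and `s_att` over
# [m, m + d] (plus padding), so that the window pair ending at t = d + m has
# exactly these memory and attentional slopes
fs_two_slopes <- function(s_mem, s_att, d = 3, m = 3, rate = 10,
                          pad_s = 1) {
  t <- seq(0, d + m + pad_s, by = 1 / rate)
  v <- ifelse(t <= m, s_mem * t, s_mem * m + s_att * (t - m))
  feature_series(v, rate, piece_id = "x", feature_name = "loudness")
}

# small synthetic corpus (shared by optimizer and evaluation tests)
small_corpus <- function(n_pieces = 4, duration_s = 60, seed = 11,
                         variant = "weighted", noise_sd = 0.1,
                         target = "trace") {
  sp <- synth_spec(n_pieces = n_pieces, duration_s = duration_s,
                   seed = seed, noise_sd = noise_sd,
                   true_params = default_true_params(variant))
  gen_corpus(sp, target = target)
}

# brute-force OLS slope over the samples of `fs` with time in (t_end - w,
# t_end], the independent oracle for the windowed slope estimator
ols_slope_oracle <- function(fs, t_end, w) {
  tt <- series_times(fs)
  sel <- tt > t_end - w + 1e-12 & tt <= t_end + 1e-12
  x <- tt[sel]; y <- fs$values[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
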