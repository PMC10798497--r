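# Synthetic data: smooth feature corpora, model-generated ground-truth
# tension, simulated multi-rater slider recordings, and audio fixtures with
# ground-truth sidecars. Every generator is a pure function of its (spec,
# seed) arguments.

#' Ground-truth parameters used by the synthetic corpus
#'
#' The weighted variant uses a global 3 s attentional / 3 s memory window;
#' the timescale variant assigns the per-feature windows characteristic of
#' continuous-rating studies (short windows for loudness and roughness,
#' long memory for tempo and onset frequency, intermediate for pitch and
#' tonal tension). Weights follow the typical ordering: loudness largest,
#' pitch/roughness/tonal tension intermediate, tempo small positive, onset
#' frequency small negative.
#'
#' @param variant \code{"weighted"} or \code{"timescale"}.
#' @return A \code{\link{model_params}}.
#' @export
default_true_params <- function(variant = c("weighted", "timescale")) {
  variant <- match.arg(variant)
  weights <- c(loudness = 1.0, roughness = 0.5, onset_frequency = -0.2,
               tempo = 0.2, pitch = 0.5, tonal_tension = 0.5)
  windows <- if (variant == "weighted") window_spec(3, 3) else list(
    loudness = window_spec(3, 3),
    roughness = window_spec(3, 4),
    onset_frequency = window_spec(3, 20),
    tempo = window_spec(3, 20),
    pitch = window_spec(5, 12),
    tonal_tension = window_spec(7, 12))
  model_params(variant = variant, windows = windows, weights = weights)
}

#' Synthetic corpus specification
#'
#' @param n_pieces Number of pieces.
#' @param duration_s Piece duration in seconds.
#' @param rate Feature rate in Hz (10).
#' @param true_params Ground-truth \code{\link{model_params}}.
#' @param noise_sd Rating noise standard deviation on the z scale.
#' @param rater_count Number of simulated raters.
#' @param rater_noise_sd Per-rater noise standard deviation (slider units).
#' @param rater_lag_s Mean rater response lag in seconds.
#' @param seed Integer seed; all outputs are reproducible bit for bit.
#' @export
synth_spec <- function(n_pieces = 10, duration_s = 90, rate = 10,
                       true_params = default_true_params("weighted"),
                       noise_sd = 0.2, rater_count = 24,
                       rater_noise_sd = 0.05, rater_lag_s = 4.5,
                       seed = 1) {
  stopifnot(n_pieces >= 1, duration_s > 0, rate > 0, rater_count >= 1)
  structure(list(n_pieces = n_pieces, duration_s = duration_s, rate = rate,
                 true_params = true_params, noise_sd = noise_sd,
                 rater_count = rater_count,
                 rater_noise_sd = rater_noise_sd,
                 rater_lag_s = rater_lag_s, seed = seed),
            class = "synth_spec")
}

# Band-limited Gaussian signal: white noise passed through an FFT brick-wall
# band-pass (0.05-0.5 Hz by default), z-scored. The band matches the time
# scales over which 1-20 s windows give distinguishable trends.
.bandlimited_signal <- function(n, rate, band = c(0.05, 0.5)) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  X[f < band[1] | f > band[2]] <- 0
  zstandardize(Re(stats::fft(X, inverse = TRUE)) / n)
}

#' Generate a synthetic feature corpus
#'
#' Per piece, six smooth, weakly correlated signals at the feature rate:
#' band-limited (0.05--0.5 Hz) Gaussian noise, z-scored. Pieces whose
#' pairwise feature correlation exceeds 0.7 in magnitude are regenerated
#' (deterministically) to keep the slope design well conditioned.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return List of \code{feature_matrix} objects, one per piece.
#' @export
gen_features <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$duration_s * spec$rate)
  feats <- canonical_features()
  lapply(seq_len(spec$n_pieces), function(i) {
    set.seed((as.double(spec$seed) * 131071 + i * 97) %%
               .Machine$integer.max)
    repeat {
      M <- vapply(feats, function(f)
        .bandlimited_signal(n, spec$rate), numeric(n))
      if (max(abs(stats::cor(M)[upper.tri(diag(6))])) < 0.7) break
    }
    feature_matrix(M, rate = spec$rate, t0 = 0,
                   piece_id = sprintf("piece_%02d", i))
  })
}

#' Generate a model-based ground-truth tension target
#'
#' The forward model: tension predicted from the features with the true
#' parameters, z-scored, plus Gaussian noise on the z scale, z-scored
#' again. An optional forward lag shifts the trace later in time, so that
#' the evaluation stage's lag handling is exercised; with the default lag
#' the trace plays the role of a mean behavioral rating.
#'
#' @param features A \code{feature_matrix}.
#' @param true_params Ground-truth \code{\link{model_params}}.
#' @param noise_sd Noise standard deviation on the z scale.
#' @param seed Integer seed.
#' @param forward_lag_s Forward lag in seconds (default 4.5).
#' @return A \code{feature_series} named \code{"mean_rating"}.
#' @export
gen_tension <- function(features, true_params, noise_sd = 0.2, seed = 1,
                        forward_lag_s = 4.5) {
  pred <- predict_tension(features, true_params)
  z <- zstandardize(pred$values)
  set.seed(seed %% .Machine$integer.max)
  y <- z + stats::rnorm(length(z), sd = noise_sd)
  feature_series(zstandardize(y), pred$rate,
                 t0 = pred$t0 + forward_lag_s,
                 piece_id = features$piece_id,
                 feature_name = "mean_rating")
}

#' Simulate multi-rater continuous slider recordings
#'
#' Each rater reproduces the true tension trace on the slider scale with a
#' personal gain, a response lag drawn around \code{rater_lag_s} (sd
#' 0.5 s), and smoothed additive noise, sampled at 60 Hz. Traces start at
#' the fixed initial slider position (30\% of the scale) with maximum
#' tension nominally at 70\%; excursions above 0.7 are allowed and the
#' slider floor clips at 0.
#'
#' @param true_tension A \code{feature_series} (e.g. from
#'   \code{\link{gen_tension}} with \code{forward_lag_s = 0}).
#' @param rater_count Number of raters.
#' @param rater_noise_sd Noise sd in slider units.
#' @param rater_lag_s Mean response lag in seconds.
#' @param seed Integer seed.
#' @param rate Slider sampling rate in Hz (default 60).
#' @return A \code{rating_set} whose grid starts at the true trace's start.
#' @export
gen_raters <- function(true_tension, rater_count = 24,
                       rater_noise_sd = 0.05, rater_lag_s = 4.5, seed = 1,
                       rate = 60) {
  stopifnot(inherits(true_tension, "feature_series"))
  set.seed(seed %% .Machine$integer.max)
  x <- true_tension$values
  tx <- series_times(true_tension)
  span <- max(x) - x[1]
  scale <- if (span > 0) (0.70 - 0.30) / span else 0
  dur <- tx[length(tx)] - tx[1] + rater_lag_s
  tt <- seq(tx[1], tx[1] + dur, by = 1 / rate)
  raters <- t(vapply(seq_len(rater_count), function(r) {
    gain <- exp(stats::rnorm(1, 0, 0.15))
    lag_r <- max(0, stats::rnorm(1, rater_lag_s, 0.5))
    base <- stats::approx(tx + lag_r, x, xout = tt, rule = 2)$y
    trace <- 0.30 + (base - x[1]) * scale * gain
    if (rater_noise_sd > 0) {
      noise <- stats::rnorm(length(tt), sd = rater_noise_sd)
      noise <- smooth_moving_average(noise, 0.5, rate = rate)
      trace <- trace + noise
    }
    trace <- pmax(trace, 0)
    trace[1] <- 0.30
    trace
  }, numeric(length(tt))))
  rating_set(raters, rate = rate, t0 = tt[1],
             piece_id = true_tension$piece_id)
}

#' Generate a full synthetic corpus
#'
#' Features plus target per piece: either the model-generated mean-rating
#' trace directly (\code{target = "trace"}, forward-lagged by
#' \code{spec$rater_lag_s}) or a simulated multi-rater
#' \code{\link{rating_set}} (\code{target = "raters"}).
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param target \code{"trace"} or \code{"raters"}.
#' @return List of pieces, each \code{list(features, ratings)}, ready for
#'   \code{\link{optimize_model}} and \code{\link{loocv}}.
#' @export
gen_corpus <- function(spec, target = c("trace", "raters")) {
  target <- match.arg(target)
  fms <- gen_features(spec)
  lapply(seq_along(fms), function(i) {
    sub_seed <- (as.double(spec$seed) * 524287 + i * 101) %%
      .Machine$integer.max
    if (target == "trace") {
      tr <- gen_tension(fms[[i]], spec$true_params, spec$noise_sd,
                        seed = sub_seed,
                        forward_lag_s = spec$rater_lag_s)
      list(features = fms[[i]], ratings = tr)
    } else {
      tr <- gen_tension(fms[[i]], spec$true_params, spec$noise_sd,
                        seed = sub_seed, forward_lag_s = 0)
      list(features = fms[[i]],
           ratings = gen_raters(tr, spec$rater_count,
                                spec$rater_noise_sd, spec$rater_lag_s,
                                seed = sub_seed + 7L))
    }
  })
}

#' Generate a synthetic audio fixture with a ground-truth sidecar
#'
#' Deterministic waveforms for exercising the feature extractors:
#' \describe{
#'   \item{sine}{pure tone; params \code{freq}, \code{duration_s},
#'     \code{amp}.}
#'   \item{am_tone}{amplitude-modulated tone; params \code{freq},
#'     \code{mod_freq}, \code{depth}, \code{duration_s}, \code{amp}.}
#'   \item{click_train}{regular clicks; params \code{rate_per_min},
#'     \code{duration_s}, \code{amp}.}
#'   \item{chord_sequence}{sum-of-sine chords from a note table; params
#'     \code{chords} (list of MIDI vectors), \code{chord_dur_s},
#'     \code{amp}.}
#'   \item{ramped_noise}{white noise with a linear amplitude ramp; params
#'     \code{duration_s}, \code{amp_from}, \code{amp_to}.}
#' }
#'
#' @param kind Fixture kind.
#' @param params Named list of kind-specific parameters.
#' @param seed Integer seed (used by the noise kinds).
#' @param rate Audio sampling rate (default 44100).
#' @return List: \code{audio} (an \code{audio_clip}) and \code{truth}
#'   (onset times, note numbers, nominal tempo, amplitude envelope, as
#'   applicable).
#' @export
gen_audio <- function(kind = c("sine", "am_tone", "click_train",
                               "chord_sequence", "ramped_noise"),
                      params = list(), seed = 1, rate = 44100) {
  kind <- match.arg(kind)
  set.seed(seed %% .Machine$integer.max)
  p <- function(name, default) if (!is.null(params[[name]]))
    params[[name]] else default
  if (kind == "sine") {
    dur <- p("duration_s", 5); f <- p("freq", 440); amp <- p("amp", 0.5)
    t <- seq(0, dur - 1 / rate, by = 1 / rate)
    s <- amp * sin(2 * pi * f * t)
    truth <- list(midi = 69 + 12 * log2(f / 440), freq = f, amp = amp)
  } else if (kind == "am_tone") {
    dur <- p("duration_s", 5); f <- p("freq", 1000)
    fm <- p("mod_freq", 70); depth <- p("depth", 1); amp <- p("amp", 0.5)
    t <- seq(0, dur - 1 / rate, by = 1 / rate)
    s <- amp * (1 + depth * sin(2 * pi * fm * t)) / (1 + depth) *
      sin(2 * pi * f * t)
    truth <- list(freq = f, mod_freq = fm, depth = depth)
  } else if (kind == "click_train") {
    dur <- p("duration_s", 10); rpm <- p("rate_per_min", 120)
    amp <- p("amp", 0.8)
    n <- round(dur * rate)
    s <- numeric(n)
    period <- 60 / rpm
    onsets <- seq(0.05, dur - 1e-9, by = period)
    onsets <- onsets[seq_len(min(length(onsets), floor(dur / period)))]
    click_len <- round(0.004 * rate)
    click <- amp * exp(-(0:(click_len - 1)) / (0.001 * rate)) *
      sin(2 * pi * 1500 * (0:(click_len - 1)) / rate)
    for (o in onsets) {
      i <- round(o * rate) + 1L
      j <- min(n, i + click_len - 1L)
      s[i:j] <- s[i:j] + click[seq_len(j - i + 1L)]
    }
    truth <- list(onset_times_s = onsets, tempo_bpm = rpm)
  } else if (kind == "chord_sequence") {
    chords <- p("chords", list(c(60, 64, 67)))
    cd <- p("chord_dur_s", 1); amp <- p("amp", 0.4)
    n_c <- round(cd * rate)
    t_c <- (0:(n_c - 1)) / rate
    env <- pmin(1, t_c / 0.02) * pmin(1, (cd - t_c) / 0.05)
    s <- numeric(0)
    notes <- list()
    for (ci in seq_along(chords)) {
      ch <- chords[[ci]]
      fr <- 440 * 2^((ch - 69) / 12)
      seg <- rowSums(vapply(fr, function(f) sin(2 * pi * f * t_c),
                            numeric(n_c)))
      s <- c(s, amp / length(ch) * env * seg)
      notes[[ci]] <- data.frame(onset_s = (ci - 1) * cd, duration_s = cd,
                                midi = ch)
    }
    truth <- list(notes = do.call(rbind, notes), chord_dur_s = cd)
  } else {                                           # ramped_noise
    dur <- p("duration_s", 5)
    a0 <- p("amp_from", 0.01); a1 <- p("amp_to", 0.5)
    n <- round(dur * rate)
    envl <- seq(a0, a1, length.out = n)
    s <- envl * stats::rnorm(n)
    truth <- list(amp_envelope = c(from = a0, to = a1))
  }
  list(audio = audio_clip(pmax(pmin(s, 1), -1), rate,
                          piece_id = paste0("synthetic_", kind)),
       truth = truth)
}

#' Write a synthetic corpus to disk in the pipeline's CSV dialects
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param out_dir Output directory; per piece,
#'   \code{<piece>.features.csv} and \code{<piece>.ratings.csv}.
#' @param target Passed to \code{\link{gen_corpus}}.
#' @export
write_corpus <- function(spec, out_dir, target = "raters") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- gen_corpus(spec, target = target)
  for (pz in corpus) {
    id <- pz$features$piece_id
    write_feature_csv(pz$features,
                      file.path(out_dir, paste0(id, ".features.csv")))
    if (inherits(pz$ratings, "rating_set")) {
      write_ratings_csv(pz$ratings,
                        file.path(out_dir, paste0(id, ".ratings.csv")))
    } else {
      df <- data.frame(time_s = series_times(pz$ratings),
                       rater_01 = pz$ratings$values)
      utils::write.csv(df, file.path(out_dir, paste0(id, ".ratings.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}

#' Read a corpus directory written by \code{\link{write_corpus}}
#' @param dir Directory of paired \code{<piece>.features.csv} /
#'   \code{<piece>.ratings.csv} files.
#' @export
read_corpus <- function(dir) {
  ff <- sort(list.files(dir, pattern = "\\.features\\.csv$",
                        full.names = TRUE))
  if (length(ff) == 0) stop("no *.features.csv files in ", dir)
  lapply(ff, function(f) {
    id <- sub("\\.features\\.csv$", "", basename(f))
    rf <- file.path(dir, paste0(id, ".ratings.csv"))
    if (!file.exists(rf)) stop("missing ratings for piece ", id)
    list(features = read_feature_csv(f, piece_id = id),
         ratings = read_ratings_csv(rf, piece_id = id))
  })
}
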