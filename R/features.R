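# Six predictor features extracted from audio, each ending in the shared
# post-processing pipeline: moving-average smoothing at the native analysis
# rate, anti-aliased block-mean downsampling to 10 Hz, z-standardization.

.check_audio <- function(audio) {
  stopifnot(inherits(audio, "audio_clip"))
  if (clip_duration(audio) <= 1)
    stop("audio must be longer than 1 s for feature extraction")
}

# smooth -> downsample to the feature rate -> z-score
postprocess_feature <- function(series, config = default_config()) {
  sm <- min(config$smooth_s, (length(series$values) - 1) / series$rate)
  if (sm >= 1 / series$rate)
    series <- smooth_moving_average(series, sm)
  if (series$rate > config$rate_features)
    series <- resample_series(series, config$rate_features)
  zstandardize(series)
}

#' Extract instantaneous loudness
#'
#' A frame-level perceptual loudness estimate in sones: the frame RMS level
#' is mapped to a sound-pressure level (full-scale sine pinned near 90 dB)
#' and then through Stevens' power law, doubling loudness per 10 dB. The
#' estimate is monotone in signal level and zero for digital silence; it
#' does not model the hearing system's frequency selectivity.
#'
#' @param audio An \code{audio_clip}.
#' @param config Pipeline configuration, see \code{\link{default_config}}.
#' @param raw Return the raw sone series instead of the smoothed,
#'   z-standardized 10 Hz series.
#' @return A \code{feature_series} named \code{"loudness"}.
#' @export
extract_loudness <- function(audio, config = default_config(), raw = FALSE) {
  .check_audio(audio)
  n_frame <- 2048L; hop <- 512L
  x2 <- audio$samples^2
  cs <- c(0, cumsum(x2))
  n <- length(x2)
  starts <- seq(1L, max(1L, n - n_frame + 1L), by = hop)
  ends <- pmin(starts + n_frame - 1L, n)
  rms <- sqrt((cs[ends + 1L] - cs[starts]) / (ends - starts + 1L))
  spl <- 94 + 20 * log10(rms + 1e-12)
  sone <- ifelse(spl > 0, 2^((spl - 40) / 10), 0)
  ser <- feature_series(sone, audio$rate / hop, t0 = 0,
                        piece_id = audio$piece_id, feature_name = "loudness")
  if (raw) return(ser)
  postprocess_feature(ser, config)
}

#' Extract roughness
#'
#' Roughness is the sensation of rapid amplitude fluctuation ("beating")
#' from closely spaced partials. Estimated here from the modulation spectrum
#' of the squared, low-passed waveform: within 200 ms frames, the energy of
#' envelope fluctuations in the 20--300 Hz band, weighted by a unimodal
#' curve peaking at 70 Hz (the maximally rough modulation rate), relative to
#' the frame's DC envelope energy, and scaled by the frame level. A pure
#' tone scores near zero; a tone fully amplitude-modulated at 70 Hz scores
#' maximally.
#'
#' @inheritParams extract_loudness
#' @return A \code{feature_series} named \code{"roughness"}.
#' @export
extract_roughness <- function(audio, config = default_config(),
                              raw = FALSE) {
  .check_audio(audio)
  # demodulate: square, low-pass below 500 Hz (FFT brick wall), decimate
  env_rate <- 2000
  x2 <- audio$samples^2
  nf <- length(x2)
  X <- stats::fft(x2)
  fr <- (seq_len(nf) - 1) / nf * audio$rate
  fr <- pmin(fr, audio$rate - fr)
  X[fr > 500] <- 0
  env <- Re(stats::fft(X, inverse = TRUE)) / nf
  dec <- max(1L, floor(audio$rate / env_rate))
  env <- env[seq(1L, nf, by = dec)]
  env_rate <- audio$rate / dec
  n_frame <- max(4L, round(0.2 * env_rate))
  hop <- max(2L, round(0.1 * env_rate))
  starts <- seq(1L, max(1L, length(env) - n_frame + 1L), by = hop)
  w <- hann_window(n_frame)
  rough <- vapply(starts, function(s) {
    fr_env <- env[s:(s + n_frame - 1L)]
    dc <- mean(fr_env)
    if (dc <= 1e-12) return(0)
    sp <- Mod(stats::fft((fr_env - dc) * w))[seq_len(n_frame %/% 2L)]
    fm <- (seq_len(n_frame %/% 2L) - 1) * env_rate / n_frame
    band <- fm >= 20 & fm <= 300
    g <- (fm / 70) * exp(1 - fm / 70)       # unit peak at 70 Hz
    depth <- sqrt(sum((sp[band] * g[band])^2)) / (dc * sum(w) / 2)
    min(depth, 2)^2 * sqrt(dc)
  }, numeric(1))
  ser <- feature_series(rough, env_rate / hop, t0 = 0,
                        piece_id = audio$piece_id,
                        feature_name = "roughness")
  if (raw) return(ser)
  postprocess_feature(ser, config)
}

#' Onset list for one audio segment
#' @param onset_times_s Strictly increasing onset times in seconds.
#' @param segment \code{"first_half"}, \code{"second_half"} or
#'   \code{"whole"}.
#' @export
onset_list <- function(onset_times_s, segment = "whole") {
  if (is.unsorted(onset_times_s, strictly = TRUE))
    stop("onset times must be strictly increasing")
  structure(list(onset_times_s = as.numeric(onset_times_s),
                 segment = segment),
            class = "onset_list")
}

#' Detect note onsets
#'
#' Thresholded peak picking on the onset-strength envelope (positive
#' spectral flux of the log-magnitude mel spectrogram, summed over bands).
#' A frame is an onset when it is a local maximum of the envelope and
#' exceeds a local moving average by a fraction of the envelope's dynamic
#' range.
#'
#' @param audio An \code{audio_clip} segment of at least 1 s.
#' @param delta Threshold above the local mean, as a fraction of the
#'   envelope maximum.
#' @param wait_s Minimum separation between reported onsets in seconds.
#' @param segment Segment label carried into the result.
#' @return An \code{onset_list} (empty, with a warning, when no peaks are
#'   found).
#' @export
detect_onsets <- function(audio, delta = 0.07, wait_s = 0.05,
                          segment = "whole") {
  .check_audio(audio)
  os <- onset_strength(audio)
  env <- os$env
  if (max(env) <= 0) {
    warning("no onset-strength peaks found; returning empty onset list")
    return(onset_list(numeric(0), segment))
  }
  env <- env / max(env)
  fr <- os$frame_rate
  k_max <- max(1L, round(0.03 * fr))
  k_avg <- max(1L, round(0.35 * fr))
  n <- length(env)
  loc_mean <- smooth_moving_average(env, (2 * k_avg + 1) / fr, rate = fr)
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k_max); hi <- min(n, i + k_max)
    env[i] >= max(env[lo:hi]) && env[i] >= loc_mean[i] + delta
  }, logical(1))
  idx <- which(is_peak)
  # enforce minimum spacing, keeping the earlier (stronger-first) peak
  if (length(idx) > 1) {
    keep <- idx[1]
    for (i in idx[-1]) if ((i - keep[length(keep)]) / fr >= wait_s)
      keep <- c(keep, i)
    idx <- keep
  }
  if (length(idx) == 0) {
    warning("no onset-strength peaks found; returning empty onset list")
    return(onset_list(numeric(0), segment))
  }
  onset_list(os$times[idx], segment)
}

# Piecewise-constant event values on a uniform grid: value of the event
# starting at onset i is held from that onset until the next.
.onset_step_values <- function(onsets, t_grid, t_start, t_end) {
  vals <- rep(0, length(t_grid))
  if (length(onsets) < 2) return(list(values = vals, degenerate = TRUE))
  durations <- diff(onsets)
  ev <- max(durations) - durations           # denser onsets score higher
  ev <- c(ev, ev[length(ev)])                # last event holds its value
  idx <- findInterval(t_grid, onsets)
  inside <- idx >= 1
  vals[inside] <- ev[idx[inside]]
  list(values = vals, degenerate = FALSE)
}

#' Extract onset frequency
#'
#' The audio is split at its midpoint and onsets are detected separately in
#' each half, making the detection robust to within-piece changes such as a
#' switch of instrumentation. In each half, event durations are the
#' differences between successive onset times, and every event's value is
#' that half's maximum event duration minus the event's own duration, held
#' constant from its onset to the next (a step function). The halves are
#' concatenated and sent through the standard pipeline.
#'
#' @inheritParams extract_loudness
#' @param per_half Use each half's own maximum event duration as the
#'   reference (default); \code{FALSE} uses the whole piece's maximum.
#' @return A \code{feature_series} named \code{"onset_frequency"}.
#' @export
extract_onset_frequency <- function(audio, config = default_config(),
                                    per_half = TRUE, raw = FALSE) {
  .check_audio(audio)
  n <- length(audio$samples)
  mid <- n %/% 2L
  dur <- clip_duration(audio)
  t_mid <- mid / audio$rate
  halves <- list(
    first_half = audio_clip(audio$samples[1:mid], audio$rate,
                            audio$piece_id),
    second_half = audio_clip(audio$samples[(mid + 1L):n], audio$rate,
                             audio$piece_id))
  onsets <- list(
    first_half = detect_onsets(halves$first_half,
                               segment = "first_half")$onset_times_s,
    second_half = detect_onsets(halves$second_half,
                                segment = "second_half")$onset_times_s +
      t_mid)
  rate <- config$rate_features
  t_grid <- seq(0, dur - 1e-9, by = 1 / rate)
  in_first <- t_grid < t_mid
  vals <- rep(0, length(t_grid))
  if (per_half) {
    for (h in c("first_half", "second_half")) {
      sel <- if (h == "first_half") in_first else !in_first
      st <- .onset_step_values(onsets[[h]], t_grid[sel], 0, dur)
      if (st$degenerate)
        warning("fewer than 2 onsets in ", h,
                "; emitting constant 0 for that half")
      vals[sel] <- st$values
    }
  } else {
    all_on <- c(onsets$first_half, onsets$second_half)
    st <- .onset_step_values(all_on, t_grid, 0, dur)
    if (st$degenerate)
      warning("fewer than 2 onsets; emitting constant 0")
    vals <- st$values
  }
  ser <- feature_series(vals, rate, t0 = 0, piece_id = audio$piece_id,
                        feature_name = "onset_frequency")
  if (raw) return(ser)
  postprocess_feature(ser, config)
}

#' Extract frame-wise tempo
#'
#' Local autocorrelation of the onset-strength envelope over a sliding
#' window yields a tempogram; the dominant lag in the 30--300 BPM range
#' gives a raw tempo, which is folded octave-wise into one cyclic tempo
#' class (here the reference octave 90--180 BPM) so that metrically
#' equivalent tempi (60/120/240) map to one value and a mid-piece switch of
#' rhythmic level does not register as a tempo change.
#'
#' @inheritParams extract_loudness
#' @param window_s Autocorrelation window length in seconds.
#' @return A \code{feature_series} named \code{"tempo"} (BPM before
#'   standardization).
#' @export
extract_tempo <- function(audio, config = default_config(), window_s = 6,
                          raw = FALSE) {
  .check_audio(audio)
  os <- onset_strength(audio)
  env <- os$env - mean(os$env)
  fr <- os$frame_rate
  W <- min(length(env), max(32L, round(window_s * fr)))
  hop <- max(1L, round(fr / 10.8))            # analysis rate > 10 Hz
  starts <- seq(1L, max(1L, length(env) - W + 1L), by = hop)
  lag_min <- max(2L, floor(fr * 60 / 300))
  lag_max <- min(W - 1L, ceiling(fr * 60 / 30))
  lags <- lag_min:lag_max
  tempo_raw <- vapply(starts, function(s) {
    seg <- env[s:(s + W - 1L)]
    if (stats::sd(seg) == 0) return(NA_real_)
    ac <- vapply(lags, function(L)
      sum(seg[1:(W - L)] * seg[(L + 1L):W]), numeric(1))
    # periodic envelopes peak at every multiple of the period; take the
    # shortest lag among near-maximal peaks so the fundamental period wins
    if (max(ac) <= 0) return(60 * fr / lags[which.max(ac)])
    60 * fr / lags[which(ac >= 0.9 * max(ac))[1]]
  }, numeric(1))
  if (all(is.na(tempo_raw))) {
    message("aperiodic audio: tempogram flat, holding the global dominant bin")
    tempo_raw[] <- 120
  }
  # fill silent windows with the running estimate (hold last, backfill head)
  if (anyNA(tempo_raw)) {
    first_ok <- which(!is.na(tempo_raw))[1]
    tempo_raw[seq_len(first_ok - 1L)] <- tempo_raw[first_ok]
    for (i in seq_along(tempo_raw)) if (is.na(tempo_raw[i]))
      tempo_raw[i] <- tempo_raw[i - 1L]
  }
  fold <- function(b) {
    while (b < 90) b <- b * 2
    while (b >= 180) b <- b / 2
    b
  }
  tempo_c <- vapply(tempo_raw, fold, numeric(1))
  ser <- feature_series(tempo_c, fr / hop, t0 = 0,
                        piece_id = audio$piece_id, feature_name = "tempo")
  if (raw) return(ser)
  postprocess_feature(ser, config)
}

#' Frame-wise multi-pitch estimates from spectral peaks
#'
#' The shared front end of the pitch and tonal-tension features.
#' @param audio An \code{audio_clip}.
#' @param fmin,fmax Pitch search range in Hz.
#' @param rel_threshold Peak threshold relative to the frame maximum.
#' @param abs_floor Absolute magnitude floor for peaks.
#' @return List: \code{pitches} (numeric vector of active MIDI note numbers
#'   per frame) and \code{times} (frame end times in seconds).
#' @export
frame_pitches <- function(audio, fmin = 55, fmax = 4000,
                          rel_threshold = 0.1, abs_floor = 1) {
  sp <- stft_mag(audio, n_fft = 4096L, hop = 512L)
  mag <- sp$mag
  freqs <- sp$freqs
  band <- freqs >= fmin & freqs <= fmax
  lo_bin <- which(band)[1]
  pitches <- lapply(seq_len(ncol(mag)), function(j) {
    m <- mag[band, j]
    mx <- max(m)
    if (mx < abs_floor) return(numeric(0))
    thr <- rel_threshold * mx
    n <- length(m)
    pk <- which(m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n] &
                  m[2:(n - 1)] >= thr) + 1L
    if (length(pk) == 0) return(numeric(0))
    # parabolic interpolation of the peak bin
    f_hat <- vapply(pk, function(i) {
      a <- m[i - 1L]; b <- m[i]; c <- m[i + 1L]
      den <- a - 2 * b + c
      d <- if (abs(den) > 1e-12) 0.5 * (a - c) / den else 0
      freqs[lo_bin + i - 1L] + d * (freqs[2] - freqs[1])
    }, numeric(1))
    69 + 12 * log2(f_hat / 440)
  })
  list(pitches = pitches, times = sp$times)
}

#' Extract mean pitch height
#'
#' Active pitches per frame are estimated by spectral-peak picking (a simple
#' polyphonic transcription front end) and reduced to one value per frame by
#' the unweighted mean on the MIDI note-number scale, so that averaging
#' happens in log-frequency space. Frames with no active pitch hold the
#' previous value; leading silence carries the first observed value, which
#' avoids artificial slope spikes at rests.
#'
#' @inheritParams extract_loudness
#' @return A \code{feature_series} named \code{"pitch"}.
#' @export
extract_pitch <- function(audio, config = default_config(), raw = FALSE) {
  .check_audio(audio)
  fp <- frame_pitches(audio)
  mean_pitch <- vapply(fp$pitches, function(p)
    if (length(p)) mean(p) else NA_real_, numeric(1))
  if (all(is.na(mean_pitch)))
    stop("pitch transcription returned no notes for piece '",
         audio$piece_id, "'")
  first_ok <- which(!is.na(mean_pitch))[1]
  mean_pitch[seq_len(first_ok - 1L)] <- mean_pitch[first_ok]
  for (i in seq_along(mean_pitch)) if (is.na(mean_pitch[i]))
    mean_pitch[i] <- mean_pitch[i - 1L]
  ser <- feature_series(mean_pitch, audio$rate / 512L, t0 = 0,
                        piece_id = audio$piece_id, feature_name = "pitch")
  if (raw) return(ser)
  postprocess_feature(ser, config)
}

#' Extract all six features on one 10 Hz grid
#'
#' Runs the six extractors, truncates all series to the shortest, and
#' returns them as one aligned, z-standardized \code{feature_matrix}. A
#' single-feature failure does not abort the piece: the failed column is
#' recorded in the \code{failed} attribute and filled with zeros; a weight
#' on an absent feature is an error at prediction time, and the remaining
#' weights are deliberately not renormalized.
#'
#' @inheritParams extract_loudness
#' @return A \code{feature_matrix} with attribute \code{failed} naming any
#'   feature whose extraction failed.
#' @export
extract_all <- function(audio, config = default_config()) {
  .check_audio(audio)
  audio <- resample_audio(audio, 44100)
  extractors <- list(
    loudness = extract_loudness,
    roughness = extract_roughness,
    onset_frequency = extract_onset_frequency,
    tempo = extract_tempo,
    pitch = extract_pitch,
    tonal_tension = extract_tonal_tension)
  failed <- character(0)
  series <- list()
  for (f in names(extractors)) {
    res <- tryCatch(extractors[[f]](audio, config = config),
                    error = function(e) {
                      message("feature '", f, "' failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) failed <- c(failed, f) else series[[f]] <- res
  }
  if (length(series) == 0) stop("all feature extractions failed")
  n_min <- min(vapply(series, length, integer(1)))
  data <- matrix(0, n_min, length(extractors),
                 dimnames = list(NULL, names(extractors)))
  for (f in names(series))
    data[, f] <- zstandardize(series[[f]]$values[seq_len(n_min)])
  out <- feature_matrix(data, rate = config$rate_features, t0 = 0,
                        piece_id = audio$piece_id)
  attr(out, "failed") <- failed
  out
}
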