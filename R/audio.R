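#' Mono audio clip
#'
#' @param samples Numeric vector in [-1, 1].
#' @param rate Sampling rate in Hz (nominal 44100).
#' @param piece_id Identifier.
#' @export
audio_clip <- function(samples, rate, piece_id = NA_character_) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be positive")
  structure(list(samples = samples, rate = rate, channels = 1L,
                 piece_id = piece_id),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.2f s @ %g Hz\n", x$piece_id,
              length(x$samples) / x$rate, x$rate))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Duration of an audio clip in seconds
#' @param x An \code{audio_clip}.
#' @export
clip_duration <- function(x) length(x$samples) / x$rate

#' Resample audio by linear interpolation
#'
#' Analysis rates here are far above the feature band, so interpolation
#' error is negligible.
#' @param audio An \code{audio_clip}.
#' @param target_rate Target sampling rate in Hz.
#' @export
resample_audio <- function(audio, target_rate = 44100) {
  if (audio$rate == target_rate) return(audio)
  n_out <- round(length(audio$samples) * target_rate / audio$rate)
  t_out <- (seq_len(n_out) - 1) / target_rate
  t_in <- (seq_along(audio$samples) - 1) / audio$rate
  audio_clip(stats::approx(t_in, audio$samples, xout = t_out, rule = 2)$y,
             target_rate, piece_id = audio$piece_id)
}

# --- short-time Fourier analysis ------------------------------------------

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Magnitude spectrogram: rows = frequency bins (0..n_fft/2), cols = frames.
# Frames are timestamped at their END time (causal convention).
stft_mag <- function(audio, n_fft = 2048L, hop = 512L) {
  x <- audio$samples
  n <- length(x)
  if (n < n_fft) x <- c(x, rep(0, n_fft - n))
  n <- length(x)
  starts <- seq(1L, n - n_fft + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + n_fft - 1L)],
                   numeric(n_fft))
  frames <- frames * hann_window(n_fft)
  spec <- stats::mvfft(frames)
  mag <- Mod(spec[1:(n_fft %/% 2L + 1L), , drop = FALSE])
  list(mag = mag,
       freqs = (0:(n_fft %/% 2L)) * audio$rate / n_fft,
       times = (starts - 1L + n_fft) / audio$rate,
       frame_rate = audio$rate / hop)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank applied to a magnitude spectrogram.
mel_filterbank <- function(freqs, n_mels = 64L, fmin = 30, fmax = NULL) {
  if (is.null(fmax)) fmax <- max(freqs)
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  fpts <- mel_to_hz(mpts)
  fb <- matrix(0, n_mels, length(freqs))
  for (i in seq_len(n_mels)) {
    lo <- fpts[i]; ce <- fpts[i + 1L]; hi <- fpts[i + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Onset-strength envelope: positive spectral flux of the log-magnitude mel
# spectrogram, summed over bands. Returns the envelope with its frame times.
onset_strength <- function(audio, n_fft = 2048L, hop = 512L, n_mels = 64L) {
  sp <- stft_mag(audio, n_fft = n_fft, hop = hop)
  fb <- mel_filterbank(sp$freqs, n_mels = n_mels)
  mel <- fb %*% sp$mag
  logmel <- log1p(1000 * mel)
  flux <- logmel[, -1L, drop = FALSE] - logmel[, -ncol(logmel), drop = FALSE]
  env <- colSums(pmax(flux, 0))
  list(env = env, times = sp$times[-1L], frame_rate = sp$frame_rate)
}
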