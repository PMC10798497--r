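#' Write a feature matrix to CSV
#'
#' Dialect: header \code{time_s,<feature>...}, UTF-8, '.' decimal.
#' @param x A \code{feature_matrix}.
#' @param path Output file.
#' @export
write_feature_csv <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  tt <- x$t0 + (seq_len(nrow(x$data)) - 1) / x$rate
  df <- data.frame(time_s = tt, x$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature matrix from CSV
#' @param path CSV with header \code{time_s,<feature>...}.
#' @param piece_id Identifier; defaults to the file name without extension.
#' @export
read_feature_csv <- function(path, piece_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (colnames(df)[1] != "time_s") stop("first column must be 'time_s'")
  tt <- df$time_s
  rate <- 1 / stats::median(diff(tt))
  if (is.null(piece_id))
    piece_id <- sub("\\.[^.]*$", "", basename(path))
  feature_matrix(as.matrix(df[, -1, drop = FALSE]), rate = round(rate, 6),
                 t0 = tt[1], piece_id = piece_id)
}

#' Write a rating set to CSV
#' @param x A \code{rating_set}.
#' @param path Output file; columns \code{time_s,rater_01..rater_k}.
#' @export
write_ratings_csv <- function(x, path) {
  stopifnot(inherits(x, "rating_set"))
  tt <- x$t0 + (seq_len(ncol(x$raters)) - 1) / x$rate
  df <- data.frame(time_s = tt, t(x$raters), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rating set from CSV
#' @param path CSV with header \code{time_s,rater_01..}.
#' @param piece_id Identifier; defaults to the file name without extension.
#' @export
read_ratings_csv <- function(path, piece_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (colnames(df)[1] != "time_s") stop("first column must be 'time_s'")
  tt <- df$time_s
  rate <- 1 / stats::median(diff(tt))
  if (is.null(piece_id))
    piece_id <- sub("\\.[^.]*$", "", basename(path))
  raters <- t(as.matrix(df[, -1, drop = FALSE]))
  rating_set(raters, rate = round(rate, 6), t0 = tt[1], piece_id = piece_id)
}

#' Write model parameters to a JSON file
#'
#' The file round-trips \code{\link{model_params}} exactly.
#' @param params A \code{model_params} object.
#' @param path Output file.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  obj <- list(
    variant = params$variant,
    windows = if (params$variant == "weighted") {
      list(attentional_s = params$windows$attentional_s,
           memory_s = params$windows$memory_s)
    } else {
      lapply(params$windows, function(w)
        list(attentional_s = w$attentional_s, memory_s = w$memory_s))
    },
    weights = as.list(params$weights),
    beta = params$beta,
    step_s = params$step_s,
    integration_window_s = params$integration_window_s,
    decay = params$decay
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from a JSON file
#' @param path JSON written by \code{\link{write_params_json}}.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  windows <- if (obj$variant == "weighted") {
    window_spec(obj$windows$attentional_s, obj$windows$memory_s)
  } else {
    lapply(obj$windows, function(w)
      window_spec(w$attentional_s, w$memory_s))
  }
  model_params(variant = obj$variant, windows = windows,
               weights = unlist(obj$weights), beta = obj$beta,
               step_s = obj$step_s,
               integration_window_s = obj$integration_window_s,
               decay = obj$decay)
}

#' Write a tension prediction to CSV (\code{time_s,tension})
#' @param x A \code{tension_series}.
#' @param path Output file.
#' @export
write_tension_csv <- function(x, path) {
  stopifnot(inherits(x, "tension_series"))
  df <- data.frame(time_s = series_times(x), tension = x$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# --- minimal RIFF/WAVE PCM I/O -------------------------------------------
# Plain 16-bit PCM read/write, sufficient for the synthetic fixtures and for
# feeding external recordings through the extraction pipeline.

#' Write a mono waveform as a 16-bit PCM WAV file
#' @param samples Numeric vector in [-1, 1].
#' @param rate Sampling rate in Hz.
#' @param path Output file.
#' @export
write_wav <- function(samples, rate, path) {
  s <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file (16- or 24-bit integer, or 32-bit float), downmixed
#' to mono
#' @param path WAV file.
#' @return An \code{audio_clip}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      extra <- sz - 16L
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = sz)
      if (sz %% 2L == 1L) readBin(con, raw(), n = 1L)
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path)
  s <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, integer(), n = length(data_raw) / 2L,
                   size = 2, signed = TRUE, endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = readBin(data_raw, numeric(), n = length(data_raw) / 4L,
                   size = 4, endian = "little"),
    stop("unsupported bit depth: ", fmt$bits))
  if (fmt$channels > 1L) {
    s <- colMeans(matrix(s, nrow = fmt$channels))
  }
  audio_clip(s, fmt$rate, piece_id = sub("\\.[^.]*$", "", basename(path)))
}
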