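# Tonal tension via the spiral-array tensile strain: pitch classes sit on a
# helix ordered by the line of fifths; a sliding window's duration-weighted
# center of effect is compared with the piece's global key center, and the
# Euclidean distance between the two is the tensile strain.

#' Line-of-fifths index for a chromatic pitch class
#'
#' C = 0 maps to index 0, then G 1, D 2, A 3, E 4, B 5, F# 6, C# 7, G# 8,
#' D# 9, A# 10, and F to -1.
#' @param pc Chromatic pitch class(es), 0 = C.
#' @export
fifths_index <- function(pc) {
  k <- (7L * (pc %% 12L)) %% 12L
  ifelse(k == 11L, -1L, k)
}

#' Spiral-array position of a pitch class
#'
#' Helix with radius 1 and vertical rise \code{h} per perfect fifth;
#' successive fifths are a quarter turn apart.
#'
#' @param pc Chromatic pitch class(es), 0 = C.
#' @param h Vertical rise per fifth (default \code{sqrt(2/15)}).
#' @return Matrix with one row per pitch class, columns x, y, z.
#' @export
spiral_position <- function(pc, h = sqrt(2 / 15)) {
  k <- fifths_index(pc)
  cbind(x = sin(k * pi / 2), y = cos(k * pi / 2), z = k * h)
}

# Duration-weighted center of effect of a set of notes.
center_of_effect <- function(midi, weights = NULL) {
  if (length(midi) == 0) return(NULL)
  if (is.null(weights)) weights <- rep(1, length(midi))
  pos <- spiral_position(round(midi) %% 12)
  w <- weights / sum(weights)
  colSums(pos * w)
}

#' Note events from frame-wise pitch estimates
#'
#' Collapses consecutive frames holding the same (rounded) pitch into note
#' events, the symbolic intermediate of the tonal-tension path.
#'
#' @param audio An \code{audio_clip}.
#' @return Data frame with \code{onset_s}, \code{duration_s}, \code{midi}.
#' @export
transcribe_notes <- function(audio) {
  stopifnot(inherits(audio, "audio_clip"))
  fp <- frame_pitches(audio)
  dt <- if (length(fp$times) > 1) fp$times[2] - fp$times[1] else 0.0116
  active <- lapply(fp$pitches, function(p) sort(unique(round(p))))
  events <- list()
  open <- list()   # midi -> onset time
  for (j in seq_along(active)) {
    now <- active[[j]]
    for (p in names(open)) {
      if (!(as.numeric(p) %in% now)) {
        events[[length(events) + 1L]] <-
          c(open[[p]], fp$times[j] - open[[p]], as.numeric(p))
        open[[p]] <- NULL
      }
    }
    for (p in now) {
      key <- as.character(p)
      if (is.null(open[[key]])) open[[key]] <- fp$times[j]
    }
  }
  t_end <- fp$times[length(fp$times)] + dt
  for (p in names(open))
    events[[length(events) + 1L]] <-
      c(open[[p]], t_end - open[[p]], as.numeric(p))
  if (length(events) == 0)
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      midi = numeric(0)))
  ev <- do.call(rbind, events)
  out <- data.frame(onset_s = ev[, 1], duration_s = ev[, 2], midi = ev[, 3])
  out[order(out$onset_s, out$midi), , drop = FALSE]
}

#' Tensile strain of a note table
#'
#' For each sliding window the duration-weighted center of effect of the
#' notes sounding in the window is computed in spiral-array space, and the
#' strain is its distance to the global key center (the duration-weighted
#' center of effect of all notes in the piece). Repeated tonic material
#' therefore scores near the per-piece minimum, while out-of-key windows
#' score high.
#'
#' @param notes Data frame with \code{onset_s}, \code{duration_s},
#'   \code{midi}.
#' @param duration_s Total duration covered by the output grid.
#' @param window_s Sliding window length in seconds (default 1).
#' @param rate Output grid rate in Hz.
#' @return A \code{feature_series} named \code{"tonal_tension"}
#'   (unstandardized strain values).
#' @export
tensile_strain <- function(notes, duration_s, window_s = 1, rate = 10) {
  if (nrow(notes) == 0) stop("note table is empty")
  key_center <- center_of_effect(notes$midi, notes$duration_s)
  t_grid <- seq(0, duration_s - 1e-9, by = 1 / rate)
  off <- notes$onset_s + notes$duration_s
  vals <- rep(NA_real_, length(t_grid))
  for (i in seq_along(t_grid)) {
    t_hi <- t_grid[i]; t_lo <- t_hi - window_s
    overlap <- pmin(off, t_hi) - pmax(notes$onset_s, t_lo)
    sel <- overlap > 0
    if (!any(sel)) next
    ce <- center_of_effect(notes$midi[sel], overlap[sel])
    vals[i] <- sqrt(sum((ce - key_center)^2))
  }
  # hold over note-free frames; backfill the head
  if (all(is.na(vals))) stop("no notes overlap the analysis grid")
  first_ok <- which(!is.na(vals))[1]
  vals[seq_len(first_ok - 1L)] <- vals[first_ok]
  for (i in seq_along(vals)) if (is.na(vals[i])) vals[i] <- vals[i - 1L]
  feature_series(vals, rate, t0 = 0, feature_name = "tonal_tension")
}

#' Extract tonal tension from audio
#'
#' Audio is transcribed to note events (\code{\link{transcribe_notes}}) and
#' the spiral-array tensile strain of a sliding symbolic window against the
#' global key center is computed (\code{\link{tensile_strain}}), then sent
#' through the standard smoothing/downsampling/z-scoring pipeline.
#'
#' @inheritParams extract_loudness
#' @param window_s Symbolic sliding-window length in seconds.
#' @return A \code{feature_series} named \code{"tonal_tension"}.
#' @export
extract_tonal_tension <- function(audio, config = default_config(),
                                  window_s = 1, raw = FALSE) {
  .check_audio(audio)
  notes <- transcribe_notes(audio)
  if (nrow(notes) == 0)
    stop("transcription returned no notes for piece '", audio$piece_id, "'")
  ser <- tensile_strain(notes, clip_duration(audio), window_s = window_s,
                        rate = config$rate_features)
  ser$piece_id <- audio$piece_id
  if (raw) return(ser)
  postprocess_feature(ser, config)
}
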