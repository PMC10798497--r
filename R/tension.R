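#' Attentional / memory window specification
#'
#' The attentional window is the sliding span over which a feature's local
#' trend (OLS slope) is computed; the memory window is the span directly
#' preceding it whose trend direction, when matching, amplifies the current
#' slope by the gain \code{beta}.
#'
#' @param attentional_s Attentional window duration in seconds (>= 1).
#' @param memory_s Memory window duration in seconds (0 disables gating).
#' @export
window_spec <- function(attentional_s, memory_s = 0) {
  if (attentional_s < 1) stop("'attentional_s' must be >= 1 second")
  if (memory_s < 0) stop("'memory_s' must be >= 0")
  structure(list(attentional_s = attentional_s, memory_s = memory_s),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> d = %g s, m = %g s\n",
              x$attentional_s, x$memory_s))
  invisible(x)
}

#' Tension-model parameters
#'
#' @param variant \code{"weighted"}: one global window pair shared by all
#'   features, individual weights. \code{"timescale"}: an individual window
#'   pair per feature in addition to the weights.
#' @param windows A single \code{\link{window_spec}} (weighted) or a named
#'   list of \code{window_spec}, one per feature (timescale).
#' @param weights Named numeric vector of feature weights; all six canonical
#'   features must be present.
#' @param beta Slope amplification gain applied when attentional and memory
#'   trends share a direction (default 5).
#' @param step_s Step between successive attentional windows in seconds
#'   (default 0.25).
#' @param integration_window_s Span of the decaying moving average that
#'   integrates overlapping slopes (default 3 s, used for both variants).
#' @param decay Geometric decay factor in (0, 1] weighting recent trends more
#'   heavily; 1 gives a plain mean (default 0.8).
#' @export
model_params <- function(variant = c("weighted", "timescale"), windows,
                         weights, beta = 5, step_s = 0.25,
                         integration_window_s = 3, decay = 0.8) {
  variant <- match.arg(variant)
  feats <- canonical_features()
  if (!all(feats %in% names(weights)))
    stop("weights must name all features: ",
         paste(setdiff(feats, names(weights)), collapse = ", "))
  weights <- weights[feats]
  if (beta < 1) stop("'beta' must be >= 1")
  if (decay <= 0 || decay > 1) stop("'decay' must be in (0, 1]")
  if (variant == "weighted") {
    stopifnot(inherits(windows, "window_spec"))
  } else {
    if (!is.list(windows) || !all(feats %in% names(windows)))
      stop("timescale variant needs one window_spec per feature")
    windows <- windows[feats]
  }
  structure(list(variant = variant, windows = windows, weights = weights,
                 beta = beta, step_s = step_s,
                 integration_window_s = integration_window_s, decay = decay),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> variant = %s, beta = %g, step = %g s, decay = %g\n",
              x$variant, x$beta, x$step_s, x$decay))
  if (x$variant == "weighted") {
    cat(sprintf("  windows: d = %g s, m = %g s\n",
                x$windows$attentional_s, x$windows$memory_s))
  } else {
    for (f in names(x$windows))
      cat(sprintf("  %-16s d = %2g s, m = %2g s\n", f,
                  x$windows[[f]]$attentional_s, x$windows[[f]]$memory_s))
  }
  cat("  weights:\n")
  for (f in names(x$weights))
    cat(sprintf("  %-16s %+.4f\n", f, x$weights[[f]]))
  invisible(x)
}

# OLS slopes of `values` over windows of length `win_s` seconds ending at the
# absolute times `end_times`; O(1) per window via prefix sums. A window
# covers samples with time in (end - win_s, end].
.window_slopes <- function(values, rate, t0, end_times, win_s) {
  n <- length(values)
  t_last <- t0 + (n - 1) / rate
  out <- rep(NA_real_, length(end_times))
  # with uniform sampling every full window of length win_s holds exactly
  # win_s * rate samples, so the OLS slope is a fixed zero-sum FIR filter
  # on the values; centering time within the window avoids the catastrophic
  # cancellation of the textbook sum formulas at large absolute times
  mm <- as.integer(round(win_s * rate))
  if (mm < 2L) return(out)
  # only windows fully inside the series carry a slope
  ok <- end_times - win_s >= t0 - 1e-9 & end_times <= t_last + 1e-9
  if (!any(ok)) return(out)
  cw <- (seq_len(mm) - (mm + 1) / 2) * 12 * rate / (mm^3 - mm)
  filt <- stats::filter(values, rev(cw), method = "convolution", sides = 1)
  i_hi <- pmin(n, as.integer(floor((end_times - t0) * rate + 1 + 1e-9)))
  out[ok] <- as.numeric(filt[i_hi[ok]])
  out
}

#' Attentional-window slopes of a feature series
#'
#' For each window end time \code{t = t0 + d, t0 + d + h, ...} the OLS slope
#' of the feature values over the span \code{(t - d, t]}, regressed on time
#' in seconds. Slopes are timestamped at the window end (causal).
#'
#' @param feature A \code{feature_series} (nominally at 10 Hz).
#' @param window A \code{\link{window_spec}}; the attentional duration
#'   \code{d} is used here, the memory duration by
#'   \code{\link{memory_gate}}.
#' @param step_s Step size \code{h} between windows in seconds (default
#'   0.25).
#' @return A \code{slope_series} with \code{$raw} slopes on the step grid.
#' @export
attentional_slopes <- function(feature, window, step_s = 0.25) {
  stopifnot(inherits(feature, "feature_series"),
            inherits(window, "window_spec"))
  d <- window$attentional_s
  dur <- series_duration(feature)
  if (d > dur)
    stop(sprintf("attentional window (%g s) does not fit in the piece (%g s)",
                 d, dur))
  if (d * feature$rate < 2)
    stop("attentional window holds fewer than 2 samples")
  end_rel <- seq(d, dur + 1e-9, by = step_s)
  end_times <- feature$t0 + end_rel
  raw <- .window_slopes(feature$values, feature$rate, feature$t0,
                        end_times, d)
  structure(list(piece_id = feature$piece_id,
                 feature_name = feature$feature_name,
                 window = window, step_s = step_s, times_s = end_times,
                 raw = raw, gated = NULL, integrated = NULL),
            class = "slope_series")
}

#' @export
print.slope_series <- function(x, ...) {
  cat(sprintf(
    "<slope_series> %s / %s: %d windows (d = %g, m = %g, h = %g)%s%s\n",
    x$piece_id, x$feature_name, length(x$times_s),
    x$window$attentional_s, x$window$memory_s, x$step_s,
    if (!is.null(x$gated)) ", gated" else "",
    if (!is.null(x$integrated)) ", integrated" else ""))
  invisible(x)
}

#' Memory-window gating of attentional slopes
#'
#' For each attentional window ending at \code{t}, the memory slope is the
#' OLS slope over the \code{m}-second span \code{(t - d - m, t - d]} that
#' directly precedes the attentional window. When the two trends share a
#' nonzero sign the attentional slope is amplified by \code{beta}; otherwise
#' it passes through unchanged. With \code{m = 0}, or where the memory span
#' would precede the piece start, gating is inactive.
#'
#' @param slopes A \code{slope_series} from \code{\link{attentional_slopes}}.
#' @param feature The originating \code{feature_series}.
#' @param beta Amplification gain (>= 1, default 5).
#' @return The \code{slope_series} with \code{$gated} filled in.
#' @export
memory_gate <- function(slopes, feature, beta = 5) {
  stopifnot(inherits(slopes, "slope_series"),
            inherits(feature, "feature_series"))
  if (beta < 1) stop("'beta' must be >= 1")
  d <- slopes$window$attentional_s
  m <- slopes$window$memory_s
  raw <- slopes$raw
  if (m == 0) {
    slopes$gated <- raw
    return(slopes)
  }
  mem_end <- slopes$times_s - d
  mem <- .window_slopes(feature$values, feature$rate, feature$t0,
                        mem_end, m)
  inside <- mem_end - m >= feature$t0 - 1e-9
  mem[!inside] <- NA_real_
  # a (numerically) zero raw or memory slope never triggers amplification
  amplify <- !is.na(mem) & !is.na(raw) & abs(raw) > 1e-12 &
    abs(mem) > 1e-12 & sign(mem) == sign(raw)
  gated <- raw
  gated[amplify] <- beta * raw[amplify]
  slopes$gated <- gated
  slopes
}

# Decaying moving average with warm-up renormalization over the available
# history; weights lambda^tau, tau = 0 (most recent) .. n_taps-1.
.decayed_mean <- function(g, n_taps, lambda) {
  k <- length(g)
  w <- lambda^(0:(n_taps - 1))
  acc <- numeric(k)
  for (j in seq_len(min(n_taps, k)) - 1L)
    acc[(j + 1L):k] <- acc[(j + 1L):k] + w[j + 1L] * g[1:(k - j)]
  norm <- rep(sum(w), k)
  head_idx <- seq_len(min(n_taps - 1L, k))
  norm[head_idx] <- cumsum(w)[head_idx]
  acc / norm
}

#' Integrate overlapping gated slopes with a decaying moving average
#'
#' Smooths the gated slope sequence so that recent trends weigh more
#' heavily: \code{S(t) = sum_tau g(t - tau h) k_tau} over
#' \code{n = integration_window_s / h} steps, with normalized geometric
#' weights \code{k_tau = lambda^tau / sum(lambda^tau)}. The warm-up frames
#' use the available shorter history, renormalized, so a constant slope is a
#' fixed point for every \code{lambda}.
#'
#' @param slopes A gated \code{slope_series}.
#' @param integration_window_s Integration span in seconds (default 3).
#' @param decay Geometric decay \code{lambda} in (0, 1]; 1 gives the plain
#'   mean of the last \code{n} slopes.
#' @return The \code{slope_series} with \code{$integrated} filled in.
#' @export
integrate_slopes <- function(slopes, integration_window_s = 3, decay = 0.8) {
  stopifnot(inherits(slopes, "slope_series"))
  if (is.null(slopes$gated))
    stop("gated slopes missing; call memory_gate() first")
  if (length(slopes$gated) == 0) stop("empty slope history")
  n_taps <- max(1L, round(integration_window_s / slopes$step_s))
  slopes$integrated <- .decayed_mean(slopes$gated, n_taps, decay)
  slopes
}

# Full per-feature slope pipeline: raw -> gated -> integrated, then drop the
# warm-up frames before t0 + d + m.
.feature_trend <- function(feature, window, params) {
  s <- attentional_slopes(feature, window, step_s = params$step_s)
  s <- memory_gate(s, feature, beta = params$beta)
  s <- integrate_slopes(s, params$integration_window_s, params$decay)
  keep <- s$times_s >= feature$t0 + window$attentional_s +
    window$memory_s - 1e-9
  list(times = s$times_s[keep], values = s$integrated[keep])
}

#' Predict continuous tension from a feature matrix
#'
#' The tension prediction is the weighted sum of the integrated feature
#' trends, \code{S(t) = sum_f w_f S_f(t)}, on the common slope grid (4 Hz at
#' the default 250 ms step). Frames during any feature's warm-up (before its
#' attentional plus memory span has elapsed) are dropped rather than
#' fabricated.
#'
#' @param features A \code{feature_matrix} with the six canonical features.
#' @param params A \code{\link{model_params}}.
#' @return A \code{tension_series}.
#' @export
predict_tension <- function(features, params) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(params, "model_params"))
  w <- params$weights
  active <- names(w)[w != 0]
  missing_active <- setdiff(active, colnames(features$data))
  if (length(missing_active) > 0)
    stop("features with nonzero weight missing from the matrix: ",
         paste(missing_active, collapse = ", "))
  h <- params$step_s
  trends <- lapply(active, function(f) {
    win <- if (params$variant == "weighted") params$windows else
      params$windows[[f]]
    .feature_trend(get_feature(features, f), win, params)
  })
  names(trends) <- active
  if (length(trends) == 0) {
    # all-zero weights: tension is identically zero on the full slope grid
    dmax <- if (params$variant == "weighted") params$windows$attentional_s
      else max(vapply(params$windows, `[[`, 0, "attentional_s"))
    dur <- (nrow(features$data) - 1) / features$rate
    tt <- features$t0 + seq(dmax, dur, by = h)
    return(structure(list(piece_id = features$piece_id, rate = 1 / h,
                          t0 = tt[1], values = rep(0, length(tt)),
                          params = params),
                     class = c("tension_series", "feature_series")))
  }
  # common lattice of slope end-times (all subsets of t0 + k*h)
  keys <- lapply(trends, function(tr) round((tr$times - features$t0) / h))
  common <- Reduce(intersect, keys)
  if (length(common) == 0)
    stop("no common time frames after warm-up; piece too short for these windows")
  common <- sort(common)
  vals <- rep(0, length(common))
  for (f in active) {
    idx <- match(common, keys[[f]])
    vals <- vals + w[[f]] * trends[[f]]$values[idx]
  }
  structure(list(piece_id = features$piece_id, rate = 1 / h,
                 t0 = features$t0 + common[1] * h, values = vals,
                 params = params),
            class = c("tension_series", "feature_series"))
}

#' @export
print.tension_series <- function(x, ...) {
  cat(sprintf("<tension_series> %s: %d frames @ %g Hz, t0 = %g s\n",
              x$piece_id, length(x$values), x$rate, x$t0))
  invisible(x)
}
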