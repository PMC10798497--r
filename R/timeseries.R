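#' Uniform-grid feature time series
#'
#' Container for one named feature's values for one piece on a uniform time
#' grid. Sample \code{i} sits at time \code{t0 + (i - 1) / rate} seconds.
#'
#' @param values Numeric vector, no missing values.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param piece_id Identifier of the musical piece.
#' @param feature_name Feature label, e.g. \code{"loudness"}.
#' @return An object of class \code{feature_series}.
#' @export
feature_series <- function(values, rate, t0 = 0, piece_id = NA_character_,
                           feature_name = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (anyNA(values)) stop("'values' must not contain missing values")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  structure(list(values = values, rate = rate, t0 = t0,
                 piece_id = piece_id, feature_name = feature_name),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s / %s: %d samples @ %g Hz, t0 = %g s\n",
              x$piece_id, x$feature_name, length(x$values), x$rate, x$t0))
  invisible(x)
}

#' @export
length.feature_series <- function(x) length(x$values)

#' Sample times of a series in seconds
#' @param x A \code{feature_series} (or any list with \code{rate}, \code{t0},
#'   \code{values}).
#' @return Numeric vector of sample times.
#' @export
series_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$rate

#' Duration of a series in seconds (span from first to last sample)
#' @param x A \code{feature_series}.
#' @export
series_duration <- function(x) (length(x$values) - 1) / x$rate

#' Population standard deviation (divisor n, the z-scoring convention)
#' @param x Numeric vector.
#' @export
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-standardize a series (population standard deviation)
#'
#' Centers to mean 0 and scales to standard deviation 1, using the
#' population convention (divide by n). A constant (zero-variance) series is
#' mapped to all zeros with a warning rather than an error, so that silent
#' segments do not abort batch runs.
#'
#' @param x A \code{feature_series} or numeric vector.
#' @param ... Unused.
#' @return Object of the same type, standardized.
#' @export
zstandardize <- function(x, ...) UseMethod("zstandardize")

#' @export
zstandardize.default <- function(x, ...) {
  m <- mean(x)
  s <- pop_sd(x)
  if (s == 0 || !is.finite(s)) {
    warning("constant series: z-score defined as all zeros")
    return(rep(0, length(x)))
  }
  (x - m) / s
}

#' @export
zstandardize.feature_series <- function(x, ...) {
  x$values <- zstandardize(x$values)
  x
}

#' Moving-average smoothing
#'
#' Each output point is the mean of the input points in a centered window of
#' \code{window_s} seconds. At the edges the window shrinks to the available
#' samples (no zero padding), which avoids biasing piece onsets where tension
#' typically builds.
#'
#' @param x A \code{feature_series} or numeric vector.
#' @param window_s Window length in seconds (>= one sample period).
#' @param rate Sampling rate in Hz; taken from \code{x} when it is a
#'   \code{feature_series}.
#' @return Smoothed object of the same type, on the same grid.
#' @export
smooth_moving_average <- function(x, window_s, rate = NULL) {
  UseMethod("smooth_moving_average")
}

#' @export
smooth_moving_average.feature_series <- function(x, window_s, rate = NULL) {
  x$values <- smooth_moving_average(x$values, window_s, rate = x$rate)
  x
}

#' @export
smooth_moving_average.default <- function(x, window_s, rate = NULL) {
  if (is.null(rate)) stop("'rate' required for a plain numeric vector")
  if (window_s < 1 / rate)
    stop("'window_s' must be at least one sample period (1/rate)")
  n <- length(x)
  w <- max(1L, round(window_s * rate))
  if (w > n)
    stop(sprintf("smoothing window (%d samples) longer than series (%d samples)",
                 w, n))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Resample a series to a new rate
#'
#' Downsampling uses an anti-aliased block mean: each output frame is the
#' mean of all original samples falling into its frame interval. Upsampling
#' (linear interpolation) is only permitted when explicitly requested, as is
#' appropriate for rating grids; for feature series it is an error.
#'
#' @param x A \code{feature_series}.
#' @param target_rate Target rate in Hz.
#' @param allow_upsample Permit interpolation to a higher rate.
#' @return A \code{feature_series} at \code{target_rate}.
#' @export
resample_series <- function(x, target_rate, allow_upsample = FALSE) {
  stopifnot(inherits(x, "feature_series"), target_rate > 0)
  if (target_rate == x$rate) return(x)
  if (target_rate > x$rate) {
    if (!allow_upsample)
      stop("upsampling beyond the original rate requires allow_upsample = TRUE")
    tt <- series_times(x)
    new_t <- seq(tt[1], tt[length(tt)], by = 1 / target_rate)
    vals <- stats::approx(tt, x$values, xout = new_t, rule = 2)$y
    return(feature_series(vals, target_rate, t0 = x$t0,
                          piece_id = x$piece_id, feature_name = x$feature_name))
  }
  rel <- (seq_along(x$values) - 1) / x$rate
  block <- floor(rel * target_rate + 1e-9) + 1L
  vals <- as.numeric(rowsum(x$values, block)) / tabulate(block)
  feature_series(vals, target_rate, t0 = x$t0,
                 piece_id = x$piece_id, feature_name = x$feature_name)
}

#' Lag-align two series
#'
#' Pairs series \code{a} (a prediction or feature) at time \code{t} with
#' series \code{b} (typically ratings) at time \code{t + lag_s}, reflecting
#' that continuous ratings lag behind the musical events that drive them.
#' Both series must share one sampling rate; absolute start times may differ.
#' A lag that is not a multiple of the sample period is rounded to the
#' nearest sample with a message.
#'
#' @param a,b \code{feature_series} objects on the same rate.
#' @param lag_s Lag in seconds (b is read \code{lag_s} later than a).
#' @return List with equal-length vectors \code{a}, \code{b} and \code{times}
#'   (times of the \code{a} samples).
#' @export
lag_align <- function(a, b, lag_s = 4.5) {
  stopifnot(inherits(a, "feature_series"), inherits(b, "feature_series"))
  if (abs(a$rate - b$rate) > 1e-9)
    stop("lag_align requires both series on one rate; got ",
         a$rate, " and ", b$rate, " Hz")
  r <- a$rate
  k_exact <- lag_s * r
  k <- round(k_exact)
  if (abs(k_exact - k) > 1e-9)
    message(sprintf("lag %g s is not a multiple of the sample period; using %g s",
                    lag_s, k / r))
  shift <- k + round((a$t0 - b$t0) * r)
  na <- length(a$values); nb <- length(b$values)
  ia <- seq_len(na)
  keep <- ia + shift >= 1L & ia + shift <= nb
  if (!any(keep)) stop("no overlap between the two series at this lag")
  ia <- ia[keep]
  list(a = a$values[ia], b = b$values[ia + shift],
       times = a$t0 + (ia - 1) / r)
}

#' Multi-rater continuous rating set for one piece
#'
#' @param raters Numeric matrix, raters in rows, time in columns. Slider
#'   positions on a 0--1 scale; excursions above the marked maximum (0.7) are
#'   allowed.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param piece_id Identifier.
#' @return An object of class \code{rating_set}. The z-standardized mean
#'   trace over raters is stored in \code{$mean_trace} (a
#'   \code{feature_series}); see \code{\link{mean_rating}} for
#'   exclusion-aware averaging.
#' @export
rating_set <- function(raters, rate, t0 = 0, piece_id = NA_character_) {
  raters <- as.matrix(raters)
  if (anyNA(raters)) stop("ratings must not contain missing values")
  if (is.null(rownames(raters)))
    rownames(raters) <- sprintf("rater_%02d", seq_len(nrow(raters)))
  x <- structure(list(raters = raters, rate = rate, t0 = t0,
                      piece_id = piece_id, mean_trace = NULL),
                 class = "rating_set")
  x$mean_trace <- .rating_mean_trace(x)
  x
}

.rating_mean_trace <- function(x, exclude = integer(0)) {
  keep <- setdiff(seq_len(nrow(x$raters)), exclude)
  if (length(keep) == 0L) stop("all raters excluded")
  m <- colMeans(x$raters[keep, , drop = FALSE])
  feature_series(zstandardize(m), x$rate, t0 = x$t0,
                 piece_id = x$piece_id, feature_name = "mean_rating")
}

#' @export
print.rating_set <- function(x, ...) {
  cat(sprintf("<rating_set> %s: %d raters x %d samples @ %g Hz\n",
              x$piece_id, nrow(x$raters), ncol(x$raters), x$rate))
  invisible(x)
}

#' Aligned multi-feature matrix for one piece
#'
#' Holds the six predictor series of one piece on a shared uniform grid.
#'
#' @param data Numeric matrix, time in rows, one named column per feature.
#' @param rate Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @param piece_id Identifier.
#' @export
feature_matrix <- function(data, rate, t0 = 0, piece_id = NA_character_) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("feature columns must be named")
  structure(list(data = data, rate = rate, t0 = t0, piece_id = piece_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d frames @ %g Hz, features: %s\n",
              x$piece_id, nrow(x$data), x$rate,
              paste(colnames(x$data), collapse = ", ")))
  invisible(x)
}

#' Extract one feature from a feature matrix as a series
#' @param x A \code{feature_matrix}.
#' @param feature Column name.
#' @export
get_feature <- function(x, feature) {
  stopifnot(inherits(x, "feature_matrix"))
  if (!feature %in% colnames(x$data))
    stop("feature '", feature, "' not present")
  feature_series(x$data[, feature], x$rate, t0 = x$t0,
                 piece_id = x$piece_id, feature_name = feature)
}

#' Canonical feature names, in model order
#' @export
canonical_features <- function() {
  c("loudness", "roughness", "onset_frequency", "tempo", "pitch",
    "tonal_tension")
}

#' Default pipeline configuration
#'
#' @return Named list: feature rate (10 Hz), evaluation rate (2 Hz),
#'   rating-to-stimulus lag (4.5 s) and pre-downsample smoothing window (1 s).
#' @export
default_config <- function() {
  list(rate_features = 10, rate_eval = 2, lag_s = 4.5, smooth_s = 1.0)
}
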