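# Agreement and validation metrics: exclusion-aware rater averaging,
# lag-shifted Spearman correlation with Fisher-z confidence intervals, RMSE,
# leave-one-piece-out cross-validation, and ICC(2,k) inter-rater reliability.

#' Flag unresponsive raters across a corpus
#'
#' A rater whose per-piece rating range falls below \code{epsilon} (a
#' fraction of the slider scale) in at least \code{min_pieces} pieces did
#' not indicate any tension changes and is flagged for exclusion.
#'
#' @param rating_sets List of \code{rating_set} objects sharing rater rows.
#' @param epsilon Range threshold on the slider scale (default 0.01, i.e.
#'   1\% of the scale).
#' @param min_pieces Number of flat pieces required to flag (default 2).
#' @return Character vector of flagged rater names.
#' @export
flag_unresponsive <- function(rating_sets, epsilon = 0.01, min_pieces = 2) {
  stopifnot(length(rating_sets) >= 1)
  raters <- rownames(rating_sets[[1]]$raters)
  flat <- sapply(rating_sets, function(rs) {
    rng <- apply(rs$raters, 1, function(v) diff(range(v)))
    rng[raters] < epsilon
  })
  flat <- matrix(flat, nrow = length(raters))
  raters[rowSums(flat) >= min_pieces]
}

#' Mean rating trace with rater exclusion
#'
#' Averages the responsive raters per time point and z-standardizes the
#' mean, the behavioral target trace of the model.
#'
#' @param ratings A \code{rating_set}.
#' @param exclude Rater names (or indices) to exclude, e.g. from
#'   \code{\link{flag_unresponsive}}.
#' @return The \code{rating_set} with \code{$mean_trace} recomputed and an
#'   \code{excluded} field recorded.
#' @export
mean_rating <- function(ratings, exclude = character(0)) {
  stopifnot(inherits(ratings, "rating_set"))
  if (nrow(ratings$raters) < 2) stop("at least 2 raters required")
  if (is.character(exclude))
    exclude <- which(rownames(ratings$raters) %in% exclude)
  ratings$mean_trace <- .rating_mean_trace(ratings, exclude = exclude)
  ratings$excluded <- rownames(ratings$raters)[exclude]
  ratings
}

# Fisher-z CI for a correlation; `adjust` optionally applies the 1.06
# variance inflation sometimes used for Spearman's rho.
.fisher_ci <- function(rho, n, conf = 0.95, adjust = FALSE) {
  if (is.na(rho) || n <= 3 || abs(rho) >= 1) return(c(NA_real_, NA_real_))
  se <- if (adjust) sqrt(1.06 / (n - 3)) else 1 / sqrt(n - 3)
  z <- atanh(rho) + c(-1, 1) * stats::qnorm(1 - (1 - conf) / 2) * se
  tanh(z)
}

#' Lag-shifted Spearman correlation between prediction and ratings
#'
#' Both series are resampled to the evaluation rate (2 Hz), the rating is
#' read \code{lag_s} seconds later than the prediction (ratings lag behind
#' the musical events), and Spearman's rho is computed on the overlap with
#' average ranks for ties. The 95\% confidence interval uses the Fisher z
#' transform.
#'
#' @param pred A \code{tension_series} (or \code{feature_series}).
#' @param rating A \code{feature_series}, typically a z-scored mean rating.
#' @param lag_s Lag in seconds (default 4.5).
#' @param rate Evaluation rate in Hz (default 2).
#' @param ci_adjust Use the 1.06 Fisher-z variance adjustment.
#' @return List: \code{rho}, \code{ci95}, \code{p}, \code{n}. A constant
#'   input yields \code{rho = NA} (undefined) rather than an error.
#' @export
lagged_spearman <- function(pred, rating, lag_s = 4.5, rate = 2,
                            ci_adjust = FALSE) {
  pred <- resample_series(pred, rate, allow_upsample = TRUE)
  rating <- resample_series(rating, rate, allow_upsample = TRUE)
  al <- lag_align(pred, rating, lag_s)
  n <- length(al$a)
  if (n < 10) stop("overlap after lag alignment is shorter than 10 samples")
  if (pop_sd(al$a) == 0 || pop_sd(al$b) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                n = n))
  }
  ct <- suppressWarnings(stats::cor.test(al$a, al$b, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, ci95 = .fisher_ci(rho, n, adjust = ci_adjust),
       p = ct$p.value, n = n)
}

#' Root mean squared error between aligned series
#'
#' @param pred,target Numeric vectors or \code{feature_series} of equal
#'   length (z-score both for scale-free comparison).
#' @export
rmse <- function(pred, target) {
  if (inherits(pred, "feature_series")) pred <- pred$values
  if (inherits(target, "feature_series")) target <- target$values
  if (length(pred) != length(target))
    stop(sprintf("length mismatch: %d vs %d", length(pred), length(target)))
  sqrt(mean((pred - target)^2))
}

#' Score one piece against its rating trace
#'
#' Lag-shifted Spearman correlation and RMSE on z-scored traces at the
#' evaluation rate.
#' @param pred Predicted tension (\code{feature_series}).
#' @param rating Rating trace (\code{feature_series}).
#' @param lag_s Rating lag in seconds.
#' @param rate Evaluation rate in Hz.
#' @return List: \code{rho}, \code{ci95}, \code{p}, \code{rmse}.
#' @export
evaluate_piece <- function(pred, rating, lag_s = 4.5, rate = 2) {
  sp <- lagged_spearman(pred, rating, lag_s = lag_s, rate = rate)
  predr <- resample_series(pred, rate, allow_upsample = TRUE)
  ratr <- resample_series(rating, rate, allow_upsample = TRUE)
  al <- lag_align(predr, ratr, lag_s)
  list(rho = sp$rho, ci95 = sp$ci95, p = sp$p,
       rmse = rmse(zstandardize(al$a), zstandardize(al$b)))
}

#' Leave-one-piece-out cross-validation
#'
#' For each piece the model is optimized on the remaining pieces, the
#' held-out piece's tension is predicted with the fitted parameters, and
#' the prediction is scored against the piece's mean rating with the
#' lag-shifted Spearman correlation and RMSE. Per-fold parameters are kept
#' for stability analysis.
#'
#' @inheritParams optimize_model
#' @param lag_s,rate Evaluation lag and rate.
#' @return An \code{eval_report}: \code{per_piece} data frame,
#'   \code{summary} (mean/sd of rho and RMSE over completed folds), and
#'   \code{params_per_fold}.
#' @export
loocv <- function(pieces, variant = c("weighted", "timescale"), grid = NULL,
                  params = NULL, design_rate = 2, lag_s = 4.5, rate = 2,
                  weight_method = "fixed") {
  variant <- match.arg(variant)
  if (length(pieces) < 3) stop("LOOCV needs at least 3 pieces")
  ids <- vapply(pieces, function(p) as.character(p$features$piece_id), "")
  rows <- list(); fold_params <- list()
  for (i in seq_along(pieces)) {
    res <- tryCatch({
      fit <- optimize_model(pieces[-i], variant = variant, grid = grid,
                            params = params, design_rate = design_rate,
                            lag_s = lag_s, weight_method = weight_method)
      pred <- predict_tension(pieces[[i]]$features, fit$params)
      target <- if (inherits(pieces[[i]]$ratings, "rating_set"))
        pieces[[i]]$ratings$mean_trace else pieces[[i]]$ratings
      sc <- evaluate_piece(pred, target, lag_s = lag_s, rate = rate)
      list(fit = fit, score = sc)
    }, error = function(e) {
      warning("fold '", ids[i], "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      rows[[i]] <- data.frame(piece = ids[i], rho = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              p = NA_real_, rmse = NA_real_,
                              failed = TRUE)
      fold_params[i] <- list(NULL)
    } else {
      rows[[i]] <- data.frame(piece = ids[i], rho = res$score$rho,
                              ci_lo = res$score$ci95[1],
                              ci_hi = res$score$ci95[2],
                              p = res$score$p, rmse = res$score$rmse,
                              failed = FALSE)
      fold_params[[i]] <- res$fit
    }
  }
  per_piece <- do.call(rbind, rows)
  ok <- !per_piece$failed & !is.na(per_piece$rho)
  structure(list(
    per_piece = per_piece,
    summary = list(mean_rho = mean(per_piece$rho[ok]),
                   sd_rho = stats::sd(per_piece$rho[ok]),
                   mean_rmse = mean(per_piece$rmse[ok]),
                   sd_rmse = stats::sd(per_piece$rmse[ok]),
                   n_folds = length(pieces), n_completed = sum(ok)),
    params_per_fold = fold_params),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<eval_report> %d/%d folds: mean rho = %.3f (sd %.3f), mean RMSE = %.3f (sd %.3f)\n",
    s$n_completed, s$n_folds, s$mean_rho, s$sd_rho, s$mean_rmse, s$sd_rmse))
  invisible(x)
}

#' Intraclass correlation ICC(2,k)
#'
#' Reliability of the mean of k raters under a two-way random-effects
#' model, from the ANOVA mean-squares decomposition: targets are the time
#' points, raters the columns of the decomposition. The 95\% confidence
#' interval follows the standard F-based method for the single-rater ICC,
#' transformed to the k-rater average.
#'
#' @param ratings_matrix Numeric matrix, raters in rows, time points in
#'   columns (>= 2 raters, >= 3 time points), or a \code{rating_set}.
#' @param conf Confidence level (default 0.95).
#' @return List: \code{icc}, \code{ci95}, mean squares. Zero
#'   between-target variance yields \code{icc = NA} (undefined).
#' @export
icc2k <- function(ratings_matrix, conf = 0.95) {
  if (inherits(ratings_matrix, "rating_set"))
    ratings_matrix <- ratings_matrix$raters
  Y <- t(as.matrix(ratings_matrix))        # targets (time) x raters
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop("at least 2 raters required")
  if (n < 3) stop("at least 3 time points required")
  grand <- mean(Y)
  ssb <- k * sum((rowMeans(Y) - grand)^2)          # between targets
  ssc <- n * sum((colMeans(Y) - grand)^2)          # between raters
  sst <- sum((Y - grand)^2)
  sse <- sst - ssb - ssc
  msr <- ssb / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  if (msr <= 0 || denom <= 0) {
    warning("zero between-target variance: ICC undefined")
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                msr = msr, msc = msc, mse = mse))
  }
  icc_k <- (msr - mse) / denom
  # single-rater ICC(2,1) CI (Shrout & Fleiss), then average-of-k transform
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  to_k <- function(r) r * k / (1 + (k - 1) * r)
  list(icc = icc_k, ci95 = c(to_k(lo1), to_k(hi1)),
       msr = msr, msc = msc, mse = mse)
}
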