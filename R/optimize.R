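# Two-step model fitting: (1) window-size selection by penalized regression
# over a pooled design of integrated slopes at every candidate window pair,
# with per-piece intercepts handled by piece-wise centering; (2) unpenalized
# weight estimation on the selected columns with per-piece intercepts.

#' Candidate window grid
#'
#' @param variant \code{"weighted"}: attentional 1--10 s, memory 0--10 s;
#'   \code{"timescale"}: attentional 1--20 s, memory 0--20 s (1 s steps).
#' @return Data frame with columns \code{d}, \code{m}.
#' @export
window_grid <- function(variant = c("weighted", "timescale")) {
  variant <- match.arg(variant)
  if (variant == "weighted") expand.grid(d = 1:10, m = 0:10)
  else expand.grid(d = 1:20, m = 0:20)
}

# Integrated slope column for one feature at one (d, m): gated and
# integrated on the step lattice, warm-up (before t0 + d + m) dropped, then
# block-meaned to the design rate. Returns design-row indices and values.
.integrated_column <- function(raw_by_len, d, m, step_s, t0, params,
                               design_rate) {
  raw <- raw_by_len[[as.character(d)]]
  k_first_raw <- which(!is.na(raw))[1]
  if (is.na(k_first_raw)) return(NULL)
  gated <- raw
  if (m > 0) {
    mem <- raw_by_len[[as.character(m)]]
    shift <- round(d / step_s)
    mem_sh <- c(rep(NA_real_, shift), mem[seq_len(length(mem) - shift)])
    amp <- !is.na(mem_sh) & !is.na(raw) & abs(raw) > 1e-12 &
      abs(mem_sh) > 1e-12 & sign(mem_sh) == sign(raw)
    gated[amp] <- params$beta * raw[amp]
  }
  seg <- gated[k_first_raw:length(gated)]
  integ <- .decayed_mean(seg, max(1L, round(params$integration_window_s /
                                              step_s)), params$decay)
  k_seg <- k_first_raw:length(gated)
  keep <- k_seg * step_s >= d + m - 1e-9
  if (!any(keep)) return(NULL)
  integ <- integ[keep]
  rel_t <- k_seg[keep] * step_s              # relative to t0
  # anti-aliased block mean onto the design-rate lattice
  block <- floor((rel_t - rel_t[1]) * design_rate + 1e-9)
  vals <- as.numeric(rowsum(integ, block)) / tabulate(block + 1L)
  block_t <- rel_t[1] + unique(block) / design_rate
  list(j = round(block_t * design_rate) + 1L, values = vals)
}

#' Build the pooled slope design matrix
#'
#' One row per evaluation-rate time point pooled over pieces; one column per
#' (feature, attentional, memory) combination holding that combination's
#' integrated slope; the target is the z-scored mean tension rating,
#' resampled to the design rate and read \code{lag_s} later than the
#' predictors. Rows falling inside any regressor's warm-up, or beyond the
#' ratings, are dropped.
#'
#' @param pieces List of pieces; each element is a list with
#'   \code{features} (a \code{feature_matrix}) and \code{ratings} (a
#'   \code{rating_set}, or directly a \code{feature_series} target trace).
#' @param grid Data frame of candidate windows (columns \code{d},
#'   \code{m}); see \code{\link{window_grid}}.
#' @param params Base \code{\link{model_params}}-like list supplying
#'   \code{beta}, \code{step_s}, \code{integration_window_s}, \code{decay}.
#' @param design_rate Row rate in Hz (default 2, limiting autocorrelation).
#' @param lag_s Rating-to-stimulus lag in seconds (default 4.5).
#' @return A \code{slope_design}: design matrix \code{X}, target \code{y},
#'   \code{piece} labels and a \code{columns} table.
#' @export
build_design <- function(pieces, grid, params = NULL, design_rate = 2,
                         lag_s = 4.5) {
  if (is.null(params))
    params <- list(beta = 5, step_s = 0.25, integration_window_s = 3,
                   decay = 0.8)
  h <- params$step_s
  feats <- canonical_features()
  cols <- do.call(rbind, lapply(feats, function(f)
    data.frame(feature = f, d = grid$d, m = grid$m,
               stringsAsFactors = FALSE)))
  X_list <- list(); y_list <- list(); piece_list <- list()
  for (pz in pieces) {
    fm <- pz$features
    stopifnot(inherits(fm, "feature_matrix"))
    target <- if (inherits(pz$ratings, "rating_set"))
      pz$ratings$mean_trace else pz$ratings
    stopifnot(inherits(target, "feature_series"))
    if (target$rate > design_rate)
      target <- resample_series(target, design_rate)
    else if (target$rate < design_rate)
      target <- resample_series(target, design_rate, allow_upsample = TRUE)
    dur <- (nrow(fm$data) - 1) / fm$rate
    K <- floor(dur / h + 1e-9)
    lattice_t <- fm$t0 + (1:K) * h
    # raw slopes for every needed window length, shared across (d, m)
    lens <- sort(unique(c(grid$d, grid$m[grid$m > 0])))
    raw_by_feat <- lapply(feats, function(f) {
      fs <- get_feature(fm, f)
      out <- lapply(lens, function(L)
        if (L > dur) rep(NA_real_, K) else
          .window_slopes(fs$values, fs$rate, fs$t0, lattice_t, L))
      names(out) <- as.character(lens)
      out
    })
    names(raw_by_feat) <- feats
    J <- floor(dur * design_rate + 1e-9)
    row_t <- fm$t0 + (0:J) / design_rate
    Xp <- matrix(NA_real_, length(row_t), nrow(cols))
    for (ci in seq_len(nrow(cols))) {
      col <- .integrated_column(raw_by_feat[[cols$feature[ci]]],
                                cols$d[ci], cols$m[ci], h, fm$t0,
                                params, design_rate)
      if (is.null(col)) next
      ok <- col$j >= 1L & col$j <= length(row_t)
      Xp[col$j[ok], ci] <- col$values[ok]
    }
    ti <- round((row_t + lag_s - target$t0) * design_rate) + 1L
    yv <- rep(NA_real_, length(row_t))
    ok <- ti >= 1L & ti <= length(target$values)
    yv[ok] <- target$values[ti[ok]]
    keep <- stats::complete.cases(Xp) & !is.na(yv)
    if (!any(keep)) {
      warning("piece '", fm$piece_id,
              "' too short for the window grid; all rows dropped")
      next
    }
    X_list[[length(X_list) + 1L]] <- Xp[keep, , drop = FALSE]
    y_list[[length(y_list) + 1L]] <- yv[keep]
    piece_list[[length(piece_list) + 1L]] <-
      rep(as.character(fm$piece_id), sum(keep))
  }
  if (length(X_list) == 0) stop("no usable rows in any piece")
  X <- do.call(rbind, X_list)
  colnames(X) <- sprintf("%s_d%d_m%d", cols$feature, cols$d, cols$m)
  structure(list(X = X, y = unlist(y_list), piece = unlist(piece_list),
                 columns = cols, design_rate = design_rate, lag_s = lag_s,
                 params = params),
            class = "slope_design")
}

#' @export
print.slope_design <- function(x, ...) {
  cat(sprintf("<slope_design> %d rows x %d columns, %d pieces @ %g Hz\n",
              nrow(x$X), ncol(x$X), length(unique(x$piece)), x$design_rate))
  invisible(x)
}

# Frisch-Waugh handling of per-piece random intercepts: center target and
# regressors within piece before the penalized fits.
.center_by_piece <- function(M, piece) {
  if (is.null(dim(M))) return(M - stats::ave(M, piece))
  apply(M, 2, function(col) col - stats::ave(col, piece))
}

# Group lasso via block coordinate descent with within-group
# orthonormalization (columns of each group replaced by an orthonormal
# basis; selection is unaffected and coefficients are refit unpenalized
# afterwards). Objective: 1/(2n) ||y - X b||^2 + lambda * sum sqrt(p_g)
# ||b_g||.
.group_lasso_path <- function(Q_list, y, lambdas, tol = 1e-6,
                              max_iter = 1e4, stop_at_first_active = FALSE) {
  n <- length(y)
  G <- length(Q_list)
  p_g <- vapply(Q_list, ncol, integer(1))
  theta <- lapply(p_g, function(p) rep(0, p))
  r <- y
  nz_by_lambda <- vector("list", length(lambdas))
  norms_by_lambda <- vector("list", length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    for (it in seq_len(max_iter)) {
      max_delta <- 0
      for (g in seq_len(G)) {
        Qg <- Q_list[[g]]
        z <- crossprod(Qg, r) / n + theta[[g]]
        zn <- sqrt(sum(z^2))
        new_t <- if (zn <= lam * sqrt(p_g[g])) rep(0, p_g[g]) else
          as.numeric(z * (1 - lam * sqrt(p_g[g]) / zn))
        d <- new_t - theta[[g]]
        if (any(d != 0)) {
          r <- r - Qg %*% d
          theta[[g]] <- new_t
          max_delta <- max(max_delta, max(abs(d)))
        }
      }
      if (max_delta < tol) break
    }
    norms <- vapply(theta, function(t) sqrt(sum(t^2)), numeric(1))
    nz_by_lambda[[li]] <- which(norms > 0)
    norms_by_lambda[[li]] <- norms
    if (stop_at_first_active && length(nz_by_lambda[[li]]) >= 1L) {
      nz_by_lambda <- nz_by_lambda[seq_len(li)]
      norms_by_lambda <- norms_by_lambda[seq_len(li)]
      break
    }
  }
  list(nonzero = nz_by_lambda, norms = norms_by_lambda)
}

.orthonormalize_groups <- function(X, group_index) {
  n <- nrow(X)
  lapply(group_index, function(idx) {
    Q <- qr.Q(qr(X[, idx, drop = FALSE]))
    Q * sqrt(n)                       # crossprod(Q)/n = I
  })
}

#' Select one global window pair (weighted variant)
#'
#' Group-penalized regression on the piece-centered design, with the six
#' feature columns sharing one (attentional, memory) pair forming a group.
#' The penalty is raised along a geometric schedule until exactly one group
#' survives; that group's window pair is returned. If the schedule jumps
#' from several surviving groups to none, the group with the largest
#' coefficient norm at the last informative penalty is taken
#' (deterministic tie-break). A \code{weak} flag marks selections whose
#' unpenalized fit explains less than 5\% of the piece-centered target
#' variance, the null-target guard.
#'
#' @param design A weighted-variant \code{slope_design}.
#' @param n_lambda,decades Penalty schedule: geometric, \code{n_lambda}
#'   points spanning \code{decades} decades below the smallest
#'   all-zero penalty.
#' @return List: \code{window} (\code{\link{window_spec}}), \code{lambda},
#'   \code{weak}, \code{r2} and the selection \code{path}.
#' @export
select_windows_grouped <- function(design, n_lambda = 50, decades = 4) {
  stopifnot(inherits(design, "slope_design"))
  Xc <- .center_by_piece(design$X, design$piece)
  yc <- .center_by_piece(design$y, design$piece)
  combos <- unique(design$columns[, c("d", "m")])
  group_index <- lapply(seq_len(nrow(combos)), function(i)
    which(design$columns$d == combos$d[i] & design$columns$m == combos$m[i]))
  Q_list <- .orthonormalize_groups(Xc, group_index)
  n <- length(yc)
  lam_max <- max(vapply(Q_list, function(Q)
    sqrt(sum((crossprod(Q, yc) / n)^2)) / sqrt(ncol(Q)), numeric(1)))
  lambdas <- lam_max * 10^(-seq(1e-3, decades, length.out = n_lambda))
  path <- .group_lasso_path(Q_list, yc, sort(lambdas, decreasing = TRUE),
                            stop_at_first_active = TRUE)
  counts <- lengths(path$nonzero)
  sel_i <- which(counts >= 1)[1]
  if (is.na(sel_i)) stop("no group became active over the penalty schedule")
  active <- path$nonzero[[sel_i]]
  g_sel <- active[which.max(path$norms[[sel_i]][active])]
  lambda_sel <- sort(lambdas, decreasing = TRUE)[sel_i]
  sel_cols <- group_index[[g_sel]]
  fit <- stats::lm.fit(Xc[, sel_cols, drop = FALSE], yc)
  r2 <- 1 - sum(fit$residuals^2) / sum(yc^2)
  list(window = window_spec(combos$d[g_sel], combos$m[g_sel]),
       lambda = lambda_sel, weak = r2 < 0.05, r2 = r2,
       path = data.frame(
         lambda = sort(lambdas, decreasing = TRUE)[seq_along(counts)],
         n_groups = counts))
}

#' Select per-feature window pairs (timescale variant)
#'
#' L1-penalized regression on the piece-centered design (no grouping, which
#' reduces multicollinearity among the highly overlapping window columns).
#' The penalty is chosen by minimizing AIC over a geometric schedule, with
#' the degrees of freedom counted as the number of nonzero coefficients
#' plus the per-piece intercepts. Each feature is then assigned the window
#' pair of its largest-magnitude nonzero coefficient; a feature with no
#' surviving column falls back to the most common selected pair and is
#' flagged.
#'
#' @param design A timescale-variant \code{slope_design}.
#' @param n_lambda,decades Penalty schedule, as in
#'   \code{\link{select_windows_grouped}}.
#' @return List: \code{windows} (named list of \code{\link{window_spec}}),
#'   \code{lambda}, \code{aic}, \code{fallback} (features assigned by
#'   fallback), \code{coefs}.
#' @export
select_windows_per_feature <- function(design, n_lambda = 50, decades = 4) {
  stopifnot(inherits(design, "slope_design"))
  Xc <- .center_by_piece(design$X, design$piece)
  yc <- .center_by_piece(design$y, design$piece)
  n <- length(yc)
  lam_max <- max(abs(crossprod(Xc, yc))) / n
  lambdas <- lam_max * 10^(-seq(1e-3, decades, length.out = n_lambda))
  fit <- glmnet::glmnet(Xc, yc, family = "gaussian", alpha = 1,
                        lambda = sort(lambdas, decreasing = TRUE),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-8)
  beta <- as.matrix(fit$beta)
  n_pieces <- length(unique(design$piece))
  rss <- colSums((yc - Xc %*% beta)^2)
  k <- colSums(beta != 0) + n_pieces
  aic <- n * log(rss / n) + 2 * k
  best <- which.min(aic)
  b <- beta[, best]
  feats <- canonical_features()
  windows <- list(); fallback <- character(0)
  picked <- list()
  for (f in feats) {
    idx <- which(design$columns$feature == f & b != 0)
    if (length(idx) == 0) { windows[f] <- list(NULL); next }
    top <- idx[which.max(abs(b[idx]))]
    picked[[f]] <- c(design$columns$d[top], design$columns$m[top])
    windows[[f]] <- window_spec(design$columns$d[top],
                                design$columns$m[top])
  }
  missing <- feats[vapply(windows[feats], is.null, logical(1))]
  if (length(missing) > 0) {
    if (length(picked) == 0)
      stop("no feature received a nonzero coefficient at the AIC-optimal penalty")
    tab <- table(vapply(picked, paste, "", collapse = "_"))
    common <- strsplit(names(tab)[which.max(tab)], "_")[[1]]
    for (f in missing) {
      windows[[f]] <- window_spec(as.numeric(common[1]),
                                  as.numeric(common[2]))
      fallback <- c(fallback, f)
      warning("feature '", f, "' had no nonzero coefficient; assigned the ",
              "most common selected window pair")
    }
  }
  list(windows = windows[feats], lambda = fit$lambda[best],
       aic = aic[best], fallback = fallback, coefs = b,
       aic_path = data.frame(lambda = fit$lambda, aic = aic,
                             nonzero = colSums(beta != 0)))
}

#' Fit feature weights with per-piece intercepts
#'
#' Linear model of the target on the six selected slope columns plus one
#' intercept per piece (fixed-effect formulation; with the balanced pooled
#' design this matches the random-intercept fit, and an explicit
#' maximum-likelihood random-intercept fit is available via
#' \code{method = "lmer"}). The marginal R-squared is the fixed-effects
#' (slope) variance over the total of slope, intercept and residual
#' variance.
#'
#' @param design A \code{slope_design} restricted to the six selected
#'   columns (one per feature).
#' @param method \code{"fixed"} (default) or \code{"lmer"}.
#' @return A \code{fit_result}-like list: \code{weights},
#'   \code{piece_intercepts}, \code{marginal_r2}, \code{se}.
#' @export
fit_weights <- function(design, method = c("fixed", "lmer")) {
  stopifnot(inherits(design, "slope_design"))
  method <- match.arg(method)
  X <- design$X
  qrX <- qr(.center_by_piece(X, design$piece))
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  piece_f <- factor(design$piece)
  if (method == "lmer") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method = 'lmer' requires the lme4 package")
    df <- data.frame(y = design$y, piece = piece_f, X)
    form <- stats::as.formula(paste("y ~", paste(colnames(X),
                                                 collapse = " + "),
                                    "+ (1 | piece)"))
    fit <- lme4::lmer(form, data = df, REML = FALSE)
    w <- lme4::fixef(fit)[colnames(X)]
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_p <- vc$vcov[vc$grp == "piece"]
    var_e <- vc$vcov[vc$grp == "Residual"]
    fixed_part <- as.numeric(X %*% w)
    var_f <- pop_sd(fixed_part)^2
    ints <- lme4::ranef(fit)$piece[, 1]
    names(ints) <- rownames(lme4::ranef(fit)$piece)
    se <- sqrt(diag(stats::vcov(fit)))[-1]
  } else {
    fit <- stats::lm(design$y ~ 0 + piece_f + X)
    cf <- stats::coef(fit)
    w <- cf[grepl("^X", names(cf))]
    names(w) <- colnames(X)
    ints <- cf[grepl("^piece_f", names(cf))]
    names(ints) <- sub("^piece_f", "", names(ints))
    fixed_part <- as.numeric(X %*% w)
    var_f <- pop_sd(fixed_part)^2
    var_p <- pop_sd(ints[design$piece])^2
    var_e <- sum(stats::residuals(fit)^2) /
      max(1, length(design$y) - length(cf))
    se <- sqrt(diag(stats::vcov(fit)))[grepl("^X", names(cf))]
    names(se) <- colnames(X)
  }
  list(weights = w, piece_intercepts = ints,
       marginal_r2 = var_f / (var_f + var_p + var_e), se = se,
       method = method)
}

# map selected columns back to per-feature weight names
.restrict_design <- function(design, windows) {
  feats <- canonical_features()
  idx <- vapply(feats, function(f) {
    w <- if (inherits(windows, "window_spec")) windows else windows[[f]]
    which(design$columns$feature == f &
            design$columns$d == w$attentional_s &
            design$columns$m == w$memory_s)
  }, integer(1))
  out <- design
  out$X <- design$X[, idx, drop = FALSE]
  colnames(out$X) <- feats
  out$columns <- design$columns[idx, , drop = FALSE]
  out
}

#' Two-step model optimization
#'
#' Builds the pooled slope design over the variant's candidate window grid,
#' selects window sizes (grouped penalty for the weighted variant, AIC-tuned
#' L1 penalty for the timescale variant), and fits the feature weights with
#' per-piece intercepts on the selected columns.
#'
#' @inheritParams build_design
#' @param variant \code{"weighted"} or \code{"timescale"}.
#' @param grid Candidate windows; defaults to \code{\link{window_grid}} for
#'   the variant.
#' @param weight_method Passed to \code{\link{fit_weights}}.
#' @return A \code{fit_result} with the selected windows, weights,
#'   intercepts, penalty, marginal R-squared and a ready-to-use
#'   \code{\link{model_params}} in \code{$params}.
#' @export
optimize_model <- function(pieces, variant = c("weighted", "timescale"),
                           grid = NULL, params = NULL, design_rate = 2,
                           lag_s = 4.5, weight_method = "fixed") {
  variant <- match.arg(variant)
  if (is.null(grid)) grid <- window_grid(variant)
  design <- build_design(pieces, grid, params = params,
                         design_rate = design_rate, lag_s = lag_s)
  if (variant == "weighted") {
    sel <- select_windows_grouped(design)
    windows <- sel$window
    lambda <- sel$lambda
    diag_sel <- sel[c("weak", "r2", "path")]
  } else {
    sel <- select_windows_per_feature(design)
    windows <- sel$windows
    lambda <- sel$lambda
    diag_sel <- sel[c("aic", "fallback", "aic_path")]
  }
  restricted <- .restrict_design(design, windows)
  wfit <- fit_weights(restricted, method = weight_method)
  bp <- design$params
  final <- model_params(variant = variant, windows = windows,
                        weights = wfit$weights, beta = bp$beta,
                        step_s = bp$step_s,
                        integration_window_s = bp$integration_window_s,
                        decay = bp$decay)
  structure(list(variant = variant, selected_windows = windows,
                 weights = wfit$weights,
                 piece_intercepts = wfit$piece_intercepts,
                 lambda = lambda, marginal_r2 = wfit$marginal_r2,
                 se = wfit$se, params = final, diagnostics = diag_sel),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> variant = %s, lambda = %.4g, marginal R2 = %.3f\n",
              x$variant, x$lambda, x$marginal_r2))
  print(x$params)
  invisible(x)
}
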