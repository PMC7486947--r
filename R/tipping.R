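#' Fit the pressure-response smoother for threshold analysis
#'
#' Penalized thin-plate regression spline of the response (relative catch
#' change, pooled over replicates and scenarios) on the pressure (bottom
#' temperature), with the basis dimension capped at `k` (default 4, guarding
#' against overfitting). The smoothing parameter is selected by GCV via
#' `mgcv::gam`. The fit stores its residuals for the residual bootstrap and
#' evaluates the smooth on a dense grid over the observed pressure range.
#'
#' @param temp Pressure values (deg C), >= 20 points with positive spread.
#' @param delta Response values (e.g. relative change in catch).
#' @param k Spline basis dimension (>= 3).
#' @param n_grid Evaluation grid size.
#' @return An object of class `threshold_fit` with elements `gam`, `grid`,
#'   `s` (smooth on grid), `d1`, `d2` (finite-difference derivatives),
#'   `fitted`, `residuals`. Confidence bands are added by
#'   [bootstrap_derivatives()].
#' @export
fit_threshold <- function(temp, delta, k = 4, n_grid = 200L) {
  ok <- is.finite(temp) & is.finite(delta)
  temp <- temp[ok]; delta <- delta[ok]
  if (length(temp) < 20L) stop("fit_threshold: need >= 20 points")
  if (stats::sd(temp) <= 0) stop("fit_threshold: pressure has no spread")
  stopifnot(k >= 3)
  d <- data.frame(x = temp, y = delta)
  g <- mgcv::gam(y ~ s(x, k = k, bs = "tp"), data = d, method = "GCV.Cp")
  grid <- seq(min(temp), max(temp), length.out = n_grid)
  s <- as.numeric(mgcv::predict.gam(g, newdata = data.frame(x = grid)))
  structure(list(gam = g, x = temp, y = delta, k = k,
                 grid = grid, s = s,
                 d1 = .fd1(s, grid), d2 = .fd2(s, grid),
                 fitted = as.numeric(stats::fitted(g)),
                 residuals = as.numeric(stats::residuals(g)),
                 bands = NULL),
            class = "threshold_fit")
}

# central finite differences with one-sided ends
.fd1 <- function(s, x) {
  n <- length(s)
  d <- numeric(n)
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (s[2] - s[1]) / (x[2] - x[1])
  d[n] <- (s[n] - s[n - 1]) / (x[n] - x[n - 1])
  d
}

.fd2 <- function(s, x) {
  h <- x[2] - x[1]
  n <- length(s)
  d <- numeric(n)
  d[2:(n - 1)] <- (s[3:n] - 2 * s[2:(n - 1)] + s[1:(n - 2)]) / h^2
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> n = %d, k = %d, grid %d over [%.3g, %.3g]%s\n",
              length(x$x), x$k, length(x$grid), min(x$grid), max(x$grid),
              if (is.null(x$bands)) "" else
                sprintf(", %d bootstrap bands", x$bands$n_boot)))
  invisible(x)
}

#' Residual-bootstrap confidence bands for the smooth and its derivatives
#'
#' Resamples the fit's residuals with replacement, forms `y* = fitted +
#' resampled residuals`, refits the penalized spline and re-evaluates the
#' smooth and its first and second finite-difference derivatives on the
#' grid; pointwise 95% bands are the 2.5 and 97.5 percentiles over
#' replicates. By default the refit holds the smoothing parameter at the
#' value selected on the original fit, which makes each replicate an exact
#' linear-operator evaluation (fast and deterministic); `refit_sp = TRUE`
#' re-selects the smoothing parameter per replicate instead. The
#' second-derivative band is additionally smoothed with a loess of span
#' `span` (default 10%) before tipping-point use.
#'
#' @param fit A [fit_threshold()] object.
#' @param n_boot Number of bootstrap replicates (>= 100; study convention
#'   1000).
#' @param seed Integer RNG seed.
#' @param span Loess span for smoothing the second-derivative band.
#' @param level Band coverage (default 0.95).
#' @param refit_sp Re-select the smoothing parameter within each replicate.
#' @return The `threshold_fit` with `bands` filled in: matrices `s`, `d1`,
#'   `d2`, `d2_smooth` (columns `lower`, `upper`), plus `n_boot` and
#'   `n_failed`.
#' @export
bootstrap_derivatives <- function(fit, n_boot = 1000L, seed = 1L,
                                  span = 0.10, level = 0.95,
                                  refit_sp = FALSE) {
  stopifnot(inherits(fit, "threshold_fit"), n_boot >= 100L)
  set.seed(as.integer(seed))
  n <- length(fit$fitted)
  grid_df <- data.frame(x = fit$grid)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  curves <- matrix(NA_real_, length(fit$grid), n_boot)
  n_failed <- 0L
  if (!refit_sp) {
    # fixed-sp Gaussian penalized spline: the grid evaluation is linear in
    # y, so precompute the projection operator once
    X <- mgcv::predict.gam(fit$gam, type = "lpmatrix")
    Xg <- mgcv::predict.gam(fit$gam, newdata = grid_df, type = "lpmatrix")
    sm <- fit$gam$smooth[[1L]]
    P <- matrix(0, ncol(X), ncol(X))
    idx <- sm$first.para:sm$last.para
    P[idx, idx] <- fit$gam$sp[1L] * sm$S[[1L]]
    A <- solve(crossprod(X) + P, t(X))
    Pg <- Xg %*% A
    Ystar <- fit$fitted +
      matrix(sample(fit$residuals, n * n_boot, replace = TRUE), n, n_boot)
    curves <- Pg %*% Ystar
  } else {
    for (b in seq_len(n_boot)) {
      ystar <- fit$fitted + sample(fit$residuals, n, replace = TRUE)
      gb <- tryCatch(
        mgcv::gam(y ~ s(x, k = fit$k, bs = "tp"),
                  data = data.frame(x = fit$x, y = ystar),
                  method = "GCV.Cp"),
        error = function(e) NULL)
      if (is.null(gb)) { n_failed <- n_failed + 1L; next }
      curves[, b] <- as.numeric(mgcv::predict.gam(gb, newdata = grid_df))
    }
    if (n_failed > 0.10 * n_boot) {
      stop(sprintf("bootstrap_derivatives: %d/%d refits failed",
                   n_failed, n_boot))
    }
    if (n_failed > 0L) {
      message(sprintf("bootstrap_derivatives: dropped %d failed replicate(s)",
                      n_failed))
      curves <- curves[, colSums(is.na(curves)) == 0L, drop = FALSE]
    }
  }

  d1b <- apply(curves, 2L, .fd1, x = fit$grid)
  d2b <- apply(curves, 2L, .fd2, x = fit$grid)
  band <- function(m) {
    q <- t(apply(m, 1L, stats::quantile, probs = probs, names = FALSE))
    colnames(q) <- c("lower", "upper")
    q
  }
  bands <- list(s = band(curves), d1 = band(d1b), d2 = band(d2b))
  sm_band <- function(v) {
    stats::predict(stats::loess(v ~ fit$grid, span = span, degree = 2))
  }
  bands$d2_smooth <- cbind(lower = sm_band(bands$d2[, "lower"]),
                           upper = sm_band(bands$d2[, "upper"]))
  bands$n_boot <- ncol(curves)
  bands$n_failed <- n_failed
  bands$level <- level
  bands$span <- span
  fit$bands <- bands
  fit
}

#' Locate the thermal tipping point from the fitted bands
#'
#' A tipping (inflection) point is a temperature where the second derivative
#' of the smooth changes sign and the (loess-smoothed) 95% bootstrap CI of
#' the second derivative excludes zero in a flanking region. Among
#' qualifying sign changes, the one whose CI is most different from zero
#' wins: the score is the maximum over the flanking region of
#' `min(|lower|, |upper|)` at grid points where both bounds share a sign;
#' ties break toward the larger `|s''|` at the candidate. Also reports the
#' grid regions where the first-derivative CI excludes zero (the significant
#' slope segments).
#'
#' @param fit A [bootstrap_derivatives()]-completed `threshold_fit`.
#' @param flank_frac Half-width of the flanking region around a sign change,
#'   as a fraction of the grid (default 0.10).
#' @return List with `tipping_temp` (numeric, or `NA` when no point
#'   qualifies), `candidates` (data frame of all sign changes with scores),
#'   `d1_significant` (logical mask over the grid) and `grid`.
#' @export
find_tipping_point <- function(fit, flank_frac = 0.10) {
  stopifnot(inherits(fit, "threshold_fit"))
  if (is.null(fit$bands)) {
    stop("find_tipping_point: run bootstrap_derivatives() first")
  }
  g <- fit$grid
  n <- length(g)
  d2 <- fit$d2
  lo <- fit$bands$d2_smooth[, "lower"]
  hi <- fit$bands$d2_smooth[, "upper"]
  excl <- (lo > 0 & hi > 0) | (lo < 0 & hi < 0)
  score_pt <- ifelse(excl, pmin(abs(lo), abs(hi)), 0)

  sgn <- sign(d2)
  changes <- which(sgn[-n] * sgn[-1L] < 0)
  w <- max(1L, round(flank_frac * n))
  cand <- lapply(changes, function(i) {
    # linear interpolation of the zero crossing
    x0 <- g[i] + (g[i + 1L] - g[i]) * d2[i] / (d2[i] - d2[i + 1L])
    fl <- max(1L, i - w):min(n, i + 1L + w)
    data.frame(temp = x0,
               score = max(score_pt[fl]),
               curv = max(abs(d2[c(i, i + 1L)])))
  })
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(temp = numeric(0), score = numeric(0), curv = numeric(0))
  qual <- cand[cand$score > 0, , drop = FALSE]
  tipping <- if (nrow(qual)) {
    qual <- qual[order(-qual$score, -qual$curv), , drop = FALSE]
    qual$temp[1L]
  } else NA_real_

  d1lo <- fit$bands$d1[, "lower"]; d1hi <- fit$bands$d1[, "upper"]
  list(tipping_temp = tipping, candidates = cand,
       d1_significant = (d1lo > 0 & d1hi > 0) | (d1lo < 0 & d1hi < 0),
       grid = g)
}
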