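#' Climate-enhanced Ricker recruitment model
#'
#' The recruits-per-spawner model
#' `ln(R_y) = alpha - beta0 * B_{y-1} + ln(B_{y-1}) + sum_j beta_j X_{j,y} + eps_y`,
#' with `eps_y ~ N(0, sigma^2)` on the log scale. Equivalently,
#' `ln(R/B)` is linear in `(-B, X)`: a Ricker stock-recruitment curve whose
#' productivity is shifted by environmental covariates (bottom temperature,
#' cold-pool extent, zooplankton indices).
#'
#' @param alpha Intercept on the log recruits-per-spawner scale.
#' @param beta0 Density-dependence coefficient (per biomass unit, >= 0 for a
#'   dome-shaped curve; the model itself does not require a sign).
#' @param betas Named numeric vector of covariate coefficients.
#' @param sigma Residual SD of the log-scale process error (>= 0).
#' @param cov Sampling covariance matrix of `c(alpha, beta0, betas)` in that
#'   order (symmetric PSD), or NULL when unknown.
#' @return An object of class `recruit_model`.
#' @export
recruit_model <- function(alpha, beta0, betas = numeric(0), sigma = 0,
                          cov = NULL) {
  stopifnot(is.numeric(alpha), is.numeric(beta0), sigma >= 0)
  if (length(betas) > 0 && is.null(names(betas))) {
    stop("recruit_model: betas must be named")
  }
  p <- 2L + length(betas)
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (!all(dim(cov) == p)) stop("recruit_model: cov has wrong dimension")
    if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov)))) {
      stop("recruit_model: cov must be symmetric")
    }
    if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("recruit_model: cov must be positive semi-definite")
    }
  }
  structure(list(alpha = unname(alpha), beta0 = unname(beta0), betas = betas,
                 sigma = sigma, cov = cov,
                 covariate_names = names(betas)),
            class = "recruit_model")
}

#' @export
print.recruit_model <- function(x, ...) {
  cat(sprintf("<recruit_model> alpha=%.4g beta0=%.4g sigma=%.4g\n",
              x$alpha, x$beta0, x$sigma))
  if (length(x$betas)) {
    cat("  covariates:",
        paste(sprintf("%s=%.4g", names(x$betas), x$betas), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Fit the climate-enhanced Ricker model to recruitment observations
#'
#' Ordinary least squares of `ln(R/B)` on `(B, X)` — the Gaussian maximum
#' likelihood fit for this model. `beta0` is the negated slope on spawning
#' biomass. The residual SD is the usual df-corrected estimator from the
#' linear model; the coefficient sampling covariance is returned on the
#' `(alpha, beta0, betas)` scale (the sign flip on the biomass slope is
#' propagated through the covariance).
#'
#' @param obs Data frame with columns `year`, `ssb` (spawning biomass in the
#'   year before recruitment, > 0), `recruits` (> 0), plus one column per
#'   covariate named in `covariates`.
#' @param covariates Character vector of covariate column names (may be
#'   empty). Defaults to the four standard indices if present in `obs`.
#' @return A `recruit_model` with `cov` filled in.
#' @export
fit_recruitment <- function(obs, covariates = NULL) {
  stopifnot(is.data.frame(obs), all(c("ssb", "recruits") %in% names(obs)))
  if (is.null(covariates)) {
    covariates <- intersect(
      c("zoop_spring", "zoop_fall", "bottom_temp", "cold_pool"), names(obs))
  }
  missing_cov <- setdiff(covariates, names(obs))
  if (length(missing_cov)) {
    stop("fit_recruitment: missing covariate columns: ",
         paste(missing_cov, collapse = ", "))
  }
  if (any(obs$ssb <= 0) || any(obs$recruits <= 0)) {
    stop("fit_recruitment: ssb and recruits must be strictly positive")
  }
  p <- 2L + length(covariates)
  if (nrow(obs) < p + 2L) {
    stop(sprintf("fit_recruitment: need at least %d observations, got %d",
                 p + 2L, nrow(obs)))
  }
  X <- cbind(`(Intercept)` = 1, ssb = obs$ssb)
  for (nm in covariates) X <- cbind(X, obs[[nm]])
  colnames(X) <- c("(Intercept)", "ssb", covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fit_recruitment: singular design; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  y <- log(obs$recruits / obs$ssb)
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- nrow(obs) - ncol(X)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX)[, order(qrX$pivot), drop = FALSE])
  vc <- sigma2 * XtXinv
  # reparameterize slope on B as -beta0: flip sign of its covariances
  J <- diag(ncol(X)); J[2L, 2L] <- -1
  vc <- J %*% vc %*% J
  betas <- co[covariates]
  names(betas) <- covariates
  recruit_model(alpha = co[["(Intercept)"]], beta0 = -co[["ssb"]],
                betas = betas, sigma = sqrt(sigma2), cov = vc)
}

#' Predict recruitment from spawning biomass and covariates
#'
#' Evaluates `R = exp(alpha - beta0 * B + ln(B) + sum beta_j X_j + eps)`.
#' Vectorized over `B` (covariates and `eps` recycled or vectorized
#' alongside).
#'
#' @param m A `recruit_model`.
#' @param B Spawning biomass (> 0), same units used when fitting.
#' @param X Named numeric vector (or list) of covariate values covering
#'   `m$covariate_names`; ignored if the model has no covariates.
#' @param eps Log-scale process-error deviate (0 for the deterministic mean
#'   curve).
#' @return Recruitment (strictly positive), same length as `B`.
#' @export
predict_recruitment <- function(m, B, X = numeric(0), eps = 0) {
  stopifnot(inherits(m, "recruit_model"))
  if (any(B <= 0)) stop("predict_recruitment: B must be > 0")
  covsum <- 0
  if (length(m$covariate_names)) {
    X <- unlist(X)
    missing_cov <- setdiff(m$covariate_names, names(X))
    if (length(missing_cov)) {
      stop("predict_recruitment: missing covariates: ",
           paste(missing_cov, collapse = ", "))
    }
    covsum <- sum(m$betas[m$covariate_names] * X[m$covariate_names])
  }
  exp(m$alpha - m$beta0 * B + log(B) + covsum + eps)
}

#' Draw recruitment-parameter replicates from the sampling distribution
#'
#' Draws `n` coefficient vectors `(alpha, beta0, betas)` from the multivariate
#' normal centred on the point estimates with the fitted sampling covariance
#' (joint draws by default; `marginal = TRUE` zeroes the cross-covariances).
#' Each draw is returned as a full `recruit_model` sharing the point
#' estimate's `sigma`. These replicates are the parameter-uncertainty axis of
#' the projection ensembles (100 draws for unfished/no-cap runs, 30 under the
#' 2 MT cap, by study convention).
#'
#' @param m A fitted `recruit_model` (with `cov`).
#' @param n Number of replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param marginal Draw each coefficient independently from its marginal
#'   normal instead of jointly.
#' @return List of `n` `recruit_model` objects.
#' @export
draw_parameter_replicates <- function(m, n, seed = 1L, marginal = FALSE) {
  stopifnot(inherits(m, "recruit_model"), n >= 1)
  if (is.null(m$cov)) stop("draw_parameter_replicates: model has no covariance")
  mu <- c(m$alpha, m$beta0, m$betas)
  vc <- m$cov
  if (marginal) vc <- diag(diag(vc), nrow = nrow(vc))
  set.seed(as.integer(seed))
  draws <- MASS::mvrnorm(n, mu = mu, Sigma = vc)
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  k <- length(m$betas)
  lapply(seq_len(n), function(r) {
    betas <- if (k > 0) {
      stats::setNames(draws[r, 2L + seq_len(k)], names(m$betas))
    } else numeric(0)
    recruit_model(alpha = draws[r, 1L], beta0 = draws[r, 2L], betas = betas,
                  sigma = m$sigma, cov = m$cov)
  })
}
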