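#' Log-linear catch-function ensemble (ABC to TAC to catch)
#'
#' Fits the two-stage quota system: per species, a log-linear regression of
#' TAC on own ABC (log, elasticity), other species' ABC (linear levels) and
#' 0/1 policy indicators; and an analogous regression of realized catch on
#' TAC. An ensemble of three members shares these point estimates (unless
#' `fgls = TRUE`) but differs in assumed residual structure: member 1 treats
#' equations as independent, member 2 links species within two residual
#' groups (seemingly-unrelated-regression style contemporaneous
#' correlations), member 3 links all species in one group. With `fgls = TRUE`
#' the grouped members take one feasible-GLS refinement pass using the
#' estimated cross-equation residual covariance.
#'
#' @param history Data frame with columns `year`, `species`, `abc`, `tac`,
#'   `catch` (tons) plus any 0/1 indicator columns; one row per species-year.
#'   Rows with non-positive ABC/TAC/catch are excluded with a warning.
#' @param indicators Character vector of indicator column names (default:
#'   every extra column).
#' @param groups Residual groupings for members 2 and 3 as a list of two
#'   lists of character vectors. Default (illustrative, configurable): member
#'   2 links the first two species, member 3 links all.
#' @param fgls Run the feasible-GLS refinement for grouped members.
#' @return An object of class `catch_function_model`.
#' @export
fit_catch_functions <- function(history, indicators = NULL, groups = NULL,
                                fgls = FALSE) {
  stopifnot(is.data.frame(history),
            all(c("year", "species", "abc", "tac", "catch") %in%
                  names(history)))
  if (is.null(indicators)) {
    indicators <- setdiff(names(history),
                          c("year", "species", "abc", "tac", "catch"))
  }
  species <- unique(history$species)
  bad <- history$abc <= 0 | history$tac <= 0 | history$catch <= 0
  if (any(bad)) {
    warning(sprintf(
      "fit_catch_functions: excluded %d year(s) with non-positive quantities",
      length(unique(history$year[bad]))))
    history <- history[!(history$year %in% history$year[bad]), ]
  }
  years <- sort(unique(history$year))
  if (length(years) < 12L) {
    stop(sprintf("fit_catch_functions: need >= 12 complete years, got %d",
                 length(years)))
  }
  wide <- .cf_widen(history, species, indicators)
  if (is.null(groups)) {
    groups <- list(
      member2 = if (length(species) >= 2L) {
        c(list(species[1:2]), as.list(species[-(1:2)]))
      } else as.list(species),
      member3 = list(species)
    )
  }
  memberships <- c(list(as.list(species)), groups)
  names(memberships) <- c("independent", "two_group", "three_group")

  stages <- list()
  for (stage in c("tac", "catch")) {
    eqs <- lapply(species, function(sp) {
      d <- .cf_design(wide, sp, species, indicators, stage)
      .cf_fit_equation(d$y, d$X)
    })
    names(eqs) <- species
    resid_mat <- vapply(eqs, `[[`, numeric(length(years)), "residuals")
    members <- lapply(memberships, function(grp) {
      mem <- list(groups = grp,
                  resid_cor = .cf_group_cor(resid_mat, grp),
                  coefs = lapply(eqs, `[[`, "coefficients"),
                  sigma = vapply(eqs, `[[`, numeric(1), "sigma"))
      if (fgls) {
        mem$coefs <- .cf_fgls(wide, species, indicators, stage, grp,
                              resid_mat, mem$coefs)
      }
      mem
    })
    stages[[stage]] <- list(equations = eqs, members = members)
  }
  structure(list(species = species, indicators = indicators,
                 years = years, stages = stages,
                 weights = rep(1 / length(memberships), length(memberships)),
                 fgls = fgls),
            class = "catch_function_model")
}

#' @export
print.catch_function_model <- function(x, ...) {
  cat(sprintf(
    "<catch_function_model> %d species, %d years, %d-member ensemble%s\n",
    length(x$species), length(x$years), length(x$weights),
    if (x$fgls) " (FGLS)" else ""))
  for (sp in x$species) {
    co <- x$stages$tac$equations[[sp]]$coefficients
    cat(sprintf("  %s: TAC elasticity on ABC = %.3f\n", sp, co[["log_own"]]))
  }
  invisible(x)
}

.cf_widen <- function(history, species, indicators) {
  years <- sort(unique(history$year))
  wide <- data.frame(year = years)
  for (sp in species) {
    d <- history[history$species == sp, ]
    i <- match(years, d$year)
    if (anyNA(i)) stop(sprintf("incomplete history for species '%s'", sp))
    wide[[paste0("abc_", sp)]] <- d$abc[i]
    wide[[paste0("tac_", sp)]] <- d$tac[i]
    wide[[paste0("catch_", sp)]] <- d$catch[i]
  }
  for (k in indicators) {
    d <- history[history$species == species[1L], ]
    wide[[k]] <- d[[k]][match(years, d$year)]
  }
  wide
}

# Regressors for one equation: intercept, log own-driver, other species'
# driver levels, indicators. stage "tac": driver = ABC; "catch": driver = TAC.
.cf_design <- function(wide, sp, species, indicators, stage) {
  driver <- if (stage == "tac") "abc" else "tac"
  response <- if (stage == "tac") "tac" else "catch"
  X <- cbind(`(Intercept)` = rep(1, nrow(wide)),
             log_own = log(wide[[paste0(driver, "_", sp)]]))
  for (o in setdiff(species, sp)) {
    X <- cbind(X, wide[[paste0(driver, "_", o)]])
    colnames(X)[ncol(X)] <- paste0("lvl_", o)
  }
  for (k in indicators) {
    X <- cbind(X, wide[[k]])
    colnames(X)[ncol(X)] <- k
  }
  list(y = log(wide[[paste0(response, "_", sp)]]), X = X)
}

# OLS with constant/aliased columns dropped (coefficient 0), so degenerate
# histories (e.g., other species held constant) fit with a warning.
.cf_fit_equation <- function(y, X) {
  keep <- rep(TRUE, ncol(X))
  sds <- apply(X, 2L, stats::sd)
  keep[-1L] <- sds[-1L] > 1e-12
  if (any(!keep)) {
    warning("catch-function fit: dropped constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    stop("catch-function fit: rank-deficient design; aliased: ",
         paste(colnames(Xk)[qrX$pivot[(qrX$rank + 1L):ncol(Xk)]],
               collapse = ", "))
  }
  fit <- stats::lm.fit(Xk, y)
  co <- stats::setNames(rep(0, ncol(X)), colnames(X))
  co[keep] <- fit$coefficients
  df <- max(1L, length(y) - ncol(Xk))
  list(coefficients = co, residuals = fit$residuals,
       sigma = sqrt(sum(fit$residuals^2) / df), dropped = colnames(X)[!keep])
}

.cf_group_cor <- function(resid_mat, grp) {
  lapply(grp, function(g) {
    g <- as.character(g)
    if (length(g) == 1L) {
      matrix(1, 1, 1, dimnames = list(g, g))
    } else {
      stats::cor(resid_mat[, g, drop = FALSE])
    }
  })
}

# One feasible-GLS pass for each multi-equation group: stack the group's
# equations, weight by the inverse of the estimated contemporaneous residual
# covariance, re-solve.
.cf_fgls <- function(wide, species, indicators, stage, grp, resid_mat,
                     coefs) {
  for (g in grp) {
    g <- as.character(g)
    if (length(g) < 2L) next
    ds <- lapply(g, function(sp) .cf_design(wide, sp, species, indicators,
                                            stage))
    keeps <- lapply(ds, function(d) {
      k <- rep(TRUE, ncol(d$X)); k[-1L] <- apply(d$X, 2, stats::sd)[-1L] > 1e-12
      k
    })
    n <- nrow(wide)
    Sigma <- stats::cov(resid_mat[, g, drop = FALSE])
    # degenerate (near-noiseless) residuals: OLS is already exact and the
    # GLS weight matrix is ill-posed; keep the OLS coefficients
    if (max(diag(Sigma)) < 1e-12 ||
        rcond(Sigma) < 1e-10) next
    Wm <- solve(Sigma)
    p <- vapply(seq_along(ds), function(i) sum(keeps[[i]]), integer(1))
    off <- c(0L, cumsum(p))
    A <- matrix(0, sum(p), sum(p))
    b <- numeric(sum(p))
    # column scaling: regressor magnitudes span ~1e6 (quota levels) to 1
    # (indicators); unscaled normal equations square that into singularity
    Xs <- list(); scl <- list()
    for (i in seq_along(g)) {
      Xi <- ds[[i]]$X[, keeps[[i]], drop = FALSE]
      d <- sqrt(colMeans(Xi^2))
      Xs[[i]] <- sweep(Xi, 2L, d, `/`)
      scl[[i]] <- d
    }
    for (i in seq_along(g)) {
      for (j in seq_along(g)) {
        A[(off[i] + 1):off[i + 1], (off[j] + 1):off[j + 1]] <-
          Wm[i, j] * crossprod(Xs[[i]], Xs[[j]])
        b[(off[i] + 1):off[i + 1]] <- b[(off[i] + 1):off[i + 1]] +
          Wm[i, j] * crossprod(Xs[[i]], ds[[j]]$y)
      }
    }
    beta <- solve(A, b)
    for (i in seq_along(g)) {
      co <- coefs[[g[i]]]
      co[keeps[[i]]] <- beta[(off[i] + 1):off[i + 1]] / scl[[i]]
      co[!keeps[[i]]] <- 0
      coefs[[g[i]]] <- co
    }
  }
  coefs
}

.cf_predict_member <- function(mem, sp, own_driver, driver_levels,
                               indicators_vals) {
  co <- mem$coefs[[sp]]
  lp <- co[["(Intercept)"]] + co[["log_own"]] * log(own_driver)
  for (nm in names(co)) {
    if (startsWith(nm, "lvl_")) {
      o <- sub("^lvl_", "", nm)
      lp <- lp + co[[nm]] * driver_levels[[o]]
    } else if (!nm %in% c("(Intercept)", "log_own")) {
      if (!nm %in% names(indicators_vals)) {
        stop(sprintf("prediction: missing indicator '%s'", nm))
      }
      lp <- lp + co[[nm]] * indicators_vals[[nm]]
    }
  }
  exp(lp)
}

.cf_predict_stage <- function(m, stage, drivers, indicators_vals, ceiling_at) {
  pred <- vapply(m$species, function(sp) {
    mean(vapply(m$stages[[stage]]$members, .cf_predict_member, numeric(1),
                sp = sp, own_driver = drivers[[sp]], driver_levels = drivers,
                indicators_vals = indicators_vals))
  }, numeric(1))
  clipped <- pred > ceiling_at[m$species]
  out <- pmin(pred, ceiling_at[m$species])
  attr(out, "clipped") <- m$species[clipped]
  out
}

#' Predict TAC from ABC through the catch-function ensemble
#'
#' Deterministic ensemble-mean (no lognormal noise, no retransformation bias
#' term) prediction of each species' TAC from the supplied ABCs, clipped at
#' ABC (TAC must not exceed ABC; clipped species are reported in the
#' `"clipped"` attribute). The 2 MT cap is applied separately by
#' [apply_cap()].
#'
#' @param m A [fit_catch_functions()] model.
#' @param abc Named vector of ABC (tons, > 0) covering `m$species`.
#' @param indicators_vals Named values for the model's indicator columns
#'   (default all zero).
#' @return Named vector of TAC (tons) with attribute `"clipped"`.
#' @export
predict_tac <- function(m, abc, indicators_vals = NULL) {
  stopifnot(inherits(m, "catch_function_model"),
            all(m$species %in% names(abc)), all(abc[m$species] > 0))
  if (is.null(indicators_vals)) {
    indicators_vals <- stats::setNames(rep(0, length(m$indicators)),
                                       m$indicators)
  }
  .cf_predict_stage(m, "tac", abc, indicators_vals, abc)
}

#' Predict realized catch from TAC through the catch-function ensemble
#'
#' @param m A [fit_catch_functions()] model.
#' @param tac Named vector of TAC (tons, > 0).
#' @param indicators_vals Named indicator values (default all zero).
#' @return Named vector of catch (tons), clipped at TAC, with attribute
#'   `"clipped"`.
#' @export
predict_catch <- function(m, tac, indicators_vals = NULL) {
  stopifnot(inherits(m, "catch_function_model"),
            all(m$species %in% names(tac)), all(tac[m$species] > 0))
  if (is.null(indicators_vals)) {
    indicators_vals <- stats::setNames(rep(0, length(m$indicators)),
                                       m$indicators)
  }
  .cf_predict_stage(m, "catch", tac, indicators_vals, tac)
}

#' Proportional reduction of TACs to the ecosystem cap
#'
#' If the modeled TACs plus the exogenous (non-modeled complex) TAC exceed
#' the cap, every modeled TAC is scaled by the single factor that makes the
#' total exactly equal the cap; relative proportions among modeled species
#' are preserved. Idempotent.
#'
#' @param tac Named vector of modeled TAC (tons, >= 0).
#' @param exogenous_other_tac Fixed TAC block for species outside the model
#'   (tons; default 0 applies the cap to the modeled species alone).
#' @param cap Ecosystem cap (tons, default 2,000,000).
#' @return Named TAC vector summing (with the exogenous block) to at most
#'   the cap.
#' @export
apply_cap <- function(tac, exogenous_other_tac = 0, cap = 2e6) {
  stopifnot(all(tac >= 0), cap > 0, exogenous_other_tac >= 0)
  if (exogenous_other_tac >= cap) {
    stop("apply_cap: exogenous TAC alone meets or exceeds the cap")
  }
  total <- sum(tac) + exogenous_other_tac
  if (total <= cap) return(tac)
  tac * (cap - exogenous_other_tac) / sum(tac)
}

#' Leave-one-out cross-validation of the catch-function ensemble
#'
#' For each historical year, refits the ensemble on the remaining years and
#' predicts the held-out year's catch from its actual TAC; accumulates, per
#' species, the sum of differences, sum of percent differences, sum of
#' squared differences and sum of squared percent differences. The same
#' metrics are computed for the naive rule catch = ABC.
#'
#' @param history As in [fit_catch_functions()] (>= 5 years).
#' @param ... Passed on to [fit_catch_functions()].
#' @return Data frame: species x model (`ensemble`, `abc_baseline`) with the
#'   four error metrics and fold counts.
#' @export
loo_cv <- function(history, ...) {
  years <- sort(unique(history$year))
  if (length(years) < 5L) stop("loo_cv: need >= 5 years")
  species <- unique(history$species)
  indicators <- setdiff(names(history),
                        c("year", "species", "abc", "tac", "catch"))
  acc <- list()
  skipped <- 0L
  for (y in years) {
    train <- history[history$year != y, ]
    test <- history[history$year == y, ]
    m <- tryCatch(
      suppressWarnings(fit_catch_functions(train, indicators = indicators,
                                           ...)),
      error = function(e) NULL)
    if (is.null(m)) {
      skipped <- skipped + 1L
      message(sprintf("loo_cv: fold %s skipped (refit failed)", y))
      next
    }
    tac_obs <- stats::setNames(test$tac, test$species)[species]
    abc_obs <- stats::setNames(test$abc, test$species)[species]
    iv <- if (length(indicators)) {
      stats::setNames(as.numeric(test[match(species[1L], test$species),
                                      indicators]), indicators)
    } else NULL
    pred <- suppressWarnings(predict_catch(m, tac_obs, iv))[species]
    obs <- stats::setNames(test$catch, test$species)[species]
    acc[[as.character(y)]] <- data.frame(
      species = species, obs = unname(obs), ensemble = unname(pred),
      abc_baseline = unname(abc_obs))
  }
  if (!length(acc)) stop("loo_cv: all folds failed")
  d <- do.call(rbind, acc)
  out <- do.call(rbind, lapply(split(d, d$species), function(s) {
    do.call(rbind, lapply(c("ensemble", "abc_baseline"), function(mod) {
      e <- s[[mod]] - s$obs
      pe <- 100 * e / s$obs
      data.frame(species = s$species[1L], model = mod,
                 sum_diff = sum(e), sum_pct_diff = sum(pe),
                 sum_sq_diff = sum(e^2), sum_sq_pct_diff = sum(pe^2),
                 n_folds = nrow(s), folds_skipped = skipped)
    }))
  }))
  rownames(out) <- NULL
  out
}
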