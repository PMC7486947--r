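# Noiseless history generated from known log-linear coefficients.
noiseless_history <- function(years = 1992:2017) {
  cfg <- study_config()
  cfg$quota_true$sd_tac <- 0
  cfg$quota_true$sd_catch <- 0
  make_quota_history(cfg, seed = 3, years = years)
}

test_that("noiseless histories refit their generating coefficients", {
  h <- noiseless_history()
  m <- fit_catch_functions(h, indicators = c("a80", "afa"))
  qt <- study_config()$quota_true
  for (sp in m$species) {
    co_t <- m$stages$tac$equations[[sp]]$coefficients
    expect_equal(co_t[["log_own"]], qt$tac_beta[[sp]], tolerance = 1e-8)
    for (o in names(qt$tac_gamma[[sp]])) {
      expect_equal(co_t[[paste0("lvl_", o)]], qt$tac_gamma[[sp]][[o]],
                   tolerance = 1e-8)
    }
    for (k in names(qt$tac_theta[[sp]])) {
      expect_equal(co_t[[k]], qt$tac_theta[[sp]][[k]], tolerance = 1e-8)
    }
    expect_lt(m$stages$tac$equations[[sp]]$sigma, 1e-10)
    co_c <- m$stages$catch$equations[[sp]]$coefficients
    expect_equal(co_c[["log_own"]], qt$catch_beta[[sp]], tolerance = 1e-8)
  }
})

test_that("identity coefficients map ABC to TAC to catch unchanged", {
  h <- noiseless_history()
  m <- fit_catch_functions(h, indicators = c("a80", "afa"))
  # overwrite with identity coefficients in every member
  for (stage in c("tac", "catch")) {
    for (i in seq_along(m$stages[[stage]]$members)) {
      for (sp in m$species) {
        co <- m$stages[[stage]]$members[[i]]$coefs[[sp]]
        co[] <- 0; co["log_own"] <- 1
        m$stages[[stage]]$members[[i]]$coefs[[sp]] <- co
      }
    }
  }
  abc <- c(pollock = 1.3e6, cod = 2.8e5, arrowtooth = 1.4e5)
  expect_equal(predict_tac(m, abc), abc, ignore_attr = TRUE)
  expect_equal(predict_catch(m, abc), abc, ignore_attr = TRUE)
  # alpha = ln 0.8, beta = 1: TAC = 0.8 ABC
  for (i in seq_along(m$stages$tac$members)) {
    co <- m$stages$tac$members[[i]]$coefs$pollock
    co["(Intercept)"] <- log(0.8)
    m$stages$tac$members[[i]]$coefs$pollock <- co
  }
  expect_equal(predict_tac(m, c(pollock = 1e6, cod = 2.8e5,
                                arrowtooth = 1.4e5))[["pollock"]], 8e5)
})

test_that("TAC predictions above ABC are clipped and flagged", {
  h <- noiseless_history()
  m <- fit_catch_functions(h, indicators = c("a80", "afa"))
  for (i in seq_along(m$stages$tac$members)) {
    co <- m$stages$tac$members[[i]]$coefs$cod
    co[] <- 0; co["log_own"] <- 1; co["(Intercept)"] <- log(1.5)
    m$stages$tac$members[[i]]$coefs$cod <- co
  }
  abc <- c(pollock = 1.3e6, cod = 2.8e5, arrowtooth = 1.4e5)
  tac <- predict_tac(m, abc)
  expect_equal(tac[["cod"]], abc[["cod"]])
  expect_true("cod" %in% attr(tac, "clipped"))
})

test_that("catch-stage indicator with negative coefficient lowers predicted catch", {
  h <- noiseless_history()
  m <- fit_catch_functions(h, indicators = c("a80", "afa"))
  for (i in seq_along(m$stages$catch$members)) {
    co <- m$stages$catch$members[[i]]$coefs$pollock
    co["a80"] <- -0.4
    m$stages$catch$members[[i]]$coefs$pollock <- co
  }
  tac <- c(pollock = 1e6, cod = 2.5e5, arrowtooth = 1e5)
  c0 <- predict_catch(m, tac, c(a80 = 0, afa = 0))
  c1 <- predict_catch(m, tac, c(a80 = 1, afa = 0))
  expect_lt(c1[["pollock"]], c0[["pollock"]])
  expect_equal(c1[["cod"]], c0[["cod"]])
})

test_that("degenerate single-species histories drop constant columns with a warning", {
  h <- noiseless_history()
  # hold the other species' quantities constant across years
  for (sp in c("cod", "arrowtooth")) {
    idx <- h$species == sp
    h$abc[idx] <- 2e5; h$tac[idx] <- 1.8e5; h$catch[idx] <- 1.6e5
  }
  w <- capture_warnings(m <- fit_catch_functions(h,
                                                 indicators = c("a80", "afa")))
  expect_true(any(grepl("constant column", w)))
  co <- m$stages$tac$equations$pollock$coefficients
  expect_equal(co[["lvl_cod"]], 0)
})

test_that("proportional cap rule: inactive below cap, exact and proportional above", {
  t1 <- c(a = 1.0e6, b = 0.5e6, c = 0.1e6)
  expect_identical(apply_cap(t1, 0, 2e6), t1)
  t2 <- c(a = 1.5e6, b = 0.8e6, c = 0.2e6)
  capped <- apply_cap(t2, 0, 2e6)
  expect_equal(sum(capped), 2e6)
  expect_equal(capped, t2 * 2 / 2.5)
  # proportions preserved to 1e-12
  expect_equal(capped[["a"]] / capped[["b"]], t2[["a"]] / t2[["b"]],
               tolerance = 1e-12)
  # idempotent
  expect_equal(apply_cap(capped, 0, 2e6), capped)
  # exogenous block counts against the cap
  capped2 <- apply_cap(t2, 5e5, 2e6)
  expect_equal(sum(capped2) + 5e5, 2e6)
  expect_error(apply_cap(t2, 2.1e6, 2e6), "exogenous")
})

test_that("own-elasticity is recovered within 0.15 in >=90% of noisy refits", {
  cfg <- study_config()
  hits <- vapply(1:200, function(s) {
    h <- make_quota_history(cfg, seed = 5000 + s)
    m <- tryCatch(fit_catch_functions(h, indicators = c("a80", "afa")),
                  error = function(e) NULL)
    if (is.null(m)) return(NA)
    abs(m$stages$tac$equations$pollock$coefficients[["log_own"]] -
          cfg$quota_true$tac_beta[["pollock"]]) <= 0.15
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.90)
})

test_that("FGLS refinement leaves noiseless fits unchanged and noisy fits close to OLS", {
  h <- noiseless_history()
  m0 <- fit_catch_functions(h, indicators = c("a80", "afa"))
  m1 <- fit_catch_functions(h, indicators = c("a80", "afa"), fgls = TRUE)
  expect_equal(m1$stages$tac$members$three_group$coefs$pollock[["log_own"]],
               m0$stages$tac$equations$pollock$coefficients[["log_own"]],
               tolerance = 1e-6)
  hn <- make_quota_history(study_config(), seed = 11)
  mg <- fit_catch_functions(hn, indicators = c("a80", "afa"), fgls = TRUE)
  ols <- mg$stages$tac$equations$pollock$coefficients[["log_own"]]
  gls <- mg$stages$tac$members$three_group$coefs$pollock[["log_own"]]
  expect_lt(abs(gls - ols), 0.2)
  expect_false(identical(gls, ols))
})

test_that("LOO-CV is exact on noiseless data and order-invariant", {
  h <- noiseless_history()
  cv <- suppressMessages(loo_cv(h))
  ens <- cv[cv$model == "ensemble", ]
  expect_lt(max(abs(ens$sum_sq_pct_diff)), 1e-10)
  # the naive catch = ABC baseline is biased high here (true catch < ABC)
  base <- cv[cv$model == "abc_baseline", ]
  expect_true(all(base$sum_sq_pct_diff > ens$sum_sq_pct_diff))
  # permuting years leaves the accumulated metrics unchanged
  hp <- h[sample(nrow(h)), ]
  cvp <- suppressMessages(loo_cv(hp))
  ordc <- order(cv$species, cv$model); ordp <- order(cvp$species, cvp$model)
  expect_equal(cv$sum_sq_diff[ordc], cvp$sum_sq_diff[ordp], tolerance = 1e-9)
})
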