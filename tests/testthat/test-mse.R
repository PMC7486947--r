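# Shared short-horizon setup: true recruitment parameters, fitted catch
# functions, reference points solved under persistence.
mse_setup <- function() {
  if (is.null(.fixture_cache$mse_setup)) {
    b <- cached_fixture(1)
    yrs <- 2018:2050
    p <- b$forcing$persistence
    up <- project_unfished(b$om, b$recruit_true, p, yrs)
    Ft <- solve_F_target(b$om, b$recruit_true, p, yrs, up$B0,
                         joint_species = c("pollock", "cod"))
    catch_model <- fit_catch_functions(b$quota_history,
                                       indicators = c("a80", "afa"))
    .fixture_cache$mse_setup <- list(
      b = b, yrs = yrs,
      policy = harvest_policy(up$B0, Ft, window = up$window),
      up = up, catch_model = catch_model,
      recruit_fit = fit_study_inputs(b)$recruit_fit)
  }
  .fixture_cache$mse_setup
}

test_that("the no-fishing variant reproduces the unfished projection", {
  s <- mse_setup()
  res <- run_scenario(s$b$om, s$b$recruit_true, s$b$forcing$persistence,
                      s$policy, "no_fishing", s$yrs)
  expect_true(all(res$catch == 0))
  expect_true(all(res$F == 0))
  ssb <- res$ssb[res$species == "pollock"]
  expect_equal(ssb, unname(s$up$ssb[, "pollock"]), tolerance = 1e-12)
})

test_that("without the cap, annual catch equals the harvest limit (ABC)", {
  s <- mse_setup()
  res <- run_scenario(s$b$om, s$b$recruit_true, s$b$forcing$persistence,
                      s$policy, "hcr_no_cap", s$yrs)
  expect_equal(res$catch, res$abc, tolerance = 1e-9)
  expect_equal(res$tac, res$abc)
  # stocks at or above target biomass are fished at exactly F_target
  high <- res$ssb >= 0.40 * s$policy$B0[res$species]
  expect_true(any(high))
  expect_equal(res$F[high],
               unname(s$policy$F_target[res$species[high]]),
               tolerance = 1e-12)
})

test_that("when the cap binds, summed TAC equals the cap exactly every year", {
  s <- mse_setup()
  tight <- s$policy
  tight$cap <- 8e5  # well below the uncapped TAC total: binds every year
  res <- run_scenario(s$b$om, s$b$recruit_true, s$b$forcing$persistence,
                      tight, "hcr_with_cap", s$yrs,
                      catch_model = s$catch_model)
  tot <- as.numeric(tapply(res$tac, res$year, sum))
  expect_equal(tot, rep(8e5, length(s$yrs)), tolerance = 1e-9)
  # realized catch matches its TAC-stage target to root-finder precision
  expect_true(all(res$catch <= res$tac * (1 + 1e-7) + 1e-6))
  expect_true(all(res$tac <= res$abc * (1 + 1e-12)))
})

test_that("capped pollock fishing mortality sits below the no-cap rate when the cap binds", {
  s <- mse_setup()
  tight <- s$policy
  tight$cap <- 8e5
  nocap <- run_scenario(s$b$om, s$b$recruit_true, s$b$forcing$persistence,
                        s$policy, "hcr_no_cap", s$yrs)
  cap <- run_scenario(s$b$om, s$b$recruit_true, s$b$forcing$persistence,
                      tight, "hcr_with_cap", s$yrs,
                      catch_model = s$catch_model)
  high_ssb <- cap$species == "pollock" &
    cap$ssb >= 0.40 * s$policy$B0[["pollock"]]
  expect_true(any(high_ssb))
  expect_true(all(cap$F[high_ssb] <
                    nocap$F[nocap$species == "pollock"][high_ssb[cap$species == "pollock"]]))
})

test_that("ensembles are reproducible and share parameter draws across variants", {
  s <- mse_setup()
  fl <- list(persistence = s$b$forcing$persistence,
             warm = s$b$forcing$rcp85_gcm2)
  args <- list(fl, s$b$om, s$recruit_fit, s$policy,
               s$catch_model, years = 2018:2032,
               variants = c("no_fishing", "hcr_no_cap"),
               n_reps = c(no_fishing = 3L, hcr_no_cap = 3L),
               base_seed = 99L)
  r1 <- suppressWarnings(do.call(run_ensemble, args))
  r2 <- suppressWarnings(do.call(run_ensemble, args))
  expect_identical(r1, r2)
  # paired draws: in the second year both variants still share the initial
  # spawning biomass, so with shared parameters and deviates the incoming
  # recruitment must be identical across variants within a replicate
  k1 <- r1[r1$variant == "no_fishing" & r1$scenario == "warm" &
             r1$year == 2019 & r1$species == "pollock", ]
  k2 <- r1[r1$variant == "hcr_no_cap" & r1$scenario == "warm" &
             r1$year == 2019 & r1$species == "pollock", ]
  expect_equal(k1$recruits[order(k1$replicate)],
               k2$recruits[order(k2$replicate)], tolerance = 1e-12)
  # replicates differ from one another
  expect_gt(sd(k1$recruits), 0)
  expect_error(run_ensemble(list(warm = fl$warm), s$b$om,
                            s$b$recruit_true, s$policy,
                            years = 2018:2020, base_seed = 1),
               "persistence")
})

test_that("closed fisheries reopen only above the cutoff", {
  # crash a stock below B20 and verify F_ABC = 0 while it is down
  s <- mse_setup()
  res <- run_scenario(s$b$om, s$b$recruit_true, s$b$forcing$rcp85_gcm3,
                      s$policy, "hcr_no_cap", 2018:2100)
  pol <- res[res$species == "pollock", ]
  below <- pol$ssb < 0.20 * s$policy$B0[["pollock"]]
  if (any(below)) {
    expect_true(all(pol$F[below] == 0))
    expect_true(all(pol$abc[below] == 0))
  }
  expect_true(all(pol$ssb > 0))
})
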