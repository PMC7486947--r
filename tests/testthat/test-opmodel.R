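test_that("thermal weight multiplier: identity at zero anomaly, linear response, floored", {
  toy <- make_toy_worked_example()
  s <- toy$om$species$toy_a
  expect_equal(weight_at_age(s, 0), s$w_base)
  s2 <- s; s2$thermal_w_sens <- -0.05
  expect_equal(weight_at_age(s2, 2), s$w_base * 0.90)
  # an extreme warm anomaly would drive weights negative; the floor holds
  expect_warning(w <- weight_at_age(s2, 100), "clamped")
  expect_equal(w, s$w_base * s$w_floor_frac)
})

test_that("predation mortality: zero without predators, linear in predator biomass", {
  om1 <- single_species_om()
  M2 <- predation_mortality(predation_config(), c(solo = 1e5), om1)
  expect_equal(M2$solo, rep(0, 6))

  toy <- make_toy_worked_example()
  om <- toy$om
  pc <- predation_config(list(list(predator = "toy_b", prey = "toy_a",
                                   coef = 2e-4, temp_slope = 0,
                                   vuln = rep(1, 5))))
  bio <- c(toy_a = 500, toy_b = 800, toy_c = 300)
  M2a <- predation_mortality(pc, bio, om, temp_anomaly = 0)
  expect_equal(M2a$toy_a, rep(2e-4 * 800, 5))
  expect_equal(M2a$toy_b, rep(0, 5))
  bio2 <- bio; bio2["toy_b"] <- 1600
  M2b <- predation_mortality(pc, bio2, om)
  expect_equal(M2b$toy_a, 2 * M2a$toy_a)
  # thermal scaling is exponential in the anomaly
  pcT <- predation_config(list(list(predator = "toy_b", prey = "toy_a",
                                    coef = 2e-4, temp_slope = 0.1,
                                    vuln = rep(1, 5))))
  M2T <- predation_mortality(pcT, bio, om, temp_anomaly = 2)
  expect_equal(M2T$toy_a, M2a$toy_a * exp(0.2))
  bad <- predation_config(list(list(predator = "ghost", prey = "toy_a",
                                    coef = 1, temp_slope = 0, vuln = 1)))
  expect_error(predation_mortality(bad, bio, om), "unknown species pair")
})

test_that("Baranov catch: closed forms, limits and monotonicity", {
  expect_equal(baranov_catch(1000, 1, 1, 0, 0.3), 0)
  # single age, S = 1, M = 0, F = 0.2: 1000 * (1 - exp(-0.2))
  expect_equal(baranov_catch(1000, 1, 1, 0.2, 0.2), 1000 * (1 - exp(-0.2)))
  # F -> infinity with M = 0 takes the whole biomass
  N <- c(500, 300); W <- c(1, 2); S <- c(1, 1)
  bigF <- 200
  expect_equal(baranov_catch(N, W, S, bigF, S * bigF), sum(N * W),
               tolerance = 1e-10)
  # strictly increasing in F at fixed M
  Fs <- seq(0.05, 2, by = 0.05)
  catches <- vapply(Fs, function(f) baranov_catch(N, W, S, f,
                                                  rep(0.2, 2) + S * f),
                    numeric(1))
  expect_true(all(diff(catches) > 0))
  expect_error(baranov_catch(100, 1, 1, 0.5, 0), "Z = 0")
})

test_that("cohorts decay exponentially under pure residual mortality", {
  om <- single_species_om()
  fc <- const_series(2001:2005, temp = 2)  # zero anomaly
  st <- init_population(om, fc, 2001)
  nxt <- advance_year(st, om, fc, single_species_recruit())
  # ages 2..5 are last year's ages 1..4 times exp(-0.3)
  expect_equal(nxt$N$solo[2:5], st$N$solo[1:4] * exp(-0.3), tolerance = 1e-12)
  # plus group accumulates its own survivors
  expect_equal(nxt$N$solo[6], (st$N$solo[5] + st$N$solo[6]) * exp(-0.3),
               tolerance = 1e-12)
  # forcing a ~zero recruitment draw empties age 1
  m0 <- list(solo = recruit_model(alpha = -700, beta0 = 1e-3, sigma = 0))
  nxt0 <- advance_year(st, om, fc, m0)
  expect_equal(nxt0$N$solo[1], 0, tolerance = 1e-250)
})

test_that("spawning biomass equals the maturity-weighted biomass after every step", {
  toy <- make_toy_worked_example()
  st <- init_population(toy$om, toy$forcing, 2001)
  for (i in 1:4) {
    for (sp in names(toy$om$species)) {
      s <- toy$om$species[[sp]]
      expect_equal(st$ssb[[sp]], sum(s$maturity * st$N[[sp]] * st$W[[sp]]),
                   tolerance = 1e-9)
    }
    st <- advance_year(st, toy$om, toy$forcing, toy$recruit_models,
                       F = toy$F)
  }
})

test_that("multispecies toy projection matches the independent plain-loop oracle", {
  toy <- make_toy_worked_example()
  got <- ebsmse:::.project_fixed_F(toy$om, toy$recruit_models, toy$forcing,
                                   toy$years, toy$F)$table
  want <- toy_oracle_trajectory(toy)
  ord <- order(got$year, got$species)
  ordw <- order(want$year, want$species)
  expect_equal(got$ssb[ord], want$ssb[ordw], tolerance = 1e-9)
  expect_equal(got$catch[ord], want$catch[ordw], tolerance = 1e-9)
})

test_that("solve_F_from_catch inverts the Baranov relationship", {
  N <- c(800, 500, 300); W <- c(0.5, 1, 1.5); S <- c(0.3, 1, 1)
  M <- rep(0.25, 3)
  expect_equal(solve_F_from_catch(N, W, S, M, 0), 0)
  Fstar <- 0.23
  catch <- baranov_catch(N, W, S, Fstar, M + S * Fstar)
  expect_equal(solve_F_from_catch(N, W, S, M, catch), Fstar,
               tolerance = 1e-8)
  # unattainable target: capped at F_max with a shortfall warning
  c_max <- baranov_catch(N, W, S, 5, M + S * 5)
  expect_warning(Fm <- solve_F_from_catch(N, W, S, M, 1.01 * c_max),
                 "shortfall")
  expect_equal(Fm, 5)
})

test_that("unfished projection yields F = 0 throughout, a window-mean B0 and equilibrium", {
  om <- single_species_om()
  fc <- const_series(2001:2080, temp = 2)
  up <- project_unfished(om, single_species_recruit(), fc, 2001:2080)
  expect_true(all(up$table$F == 0))
  expect_true(all(up$table$catch == 0))
  expect_equal(up$B0[["solo"]],
               mean(up$ssb[as.character(2076:2080), "solo"]))
  # constant forcing, no process error: SSB settles to a fixed point
  late <- up$ssb[as.character(2075:2080), "solo"]
  expect_lt(max(abs(diff(late)) / late[-1]), 1e-6)
  expect_error(project_unfished(om, single_species_recruit(), fc, 2001:2080,
                                window = c(2081, 2085)), "window")
})
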