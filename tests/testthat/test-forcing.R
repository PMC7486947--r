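test_that("degenerate generator (no trend, no noise) returns the baseline everywhere", {
  cfg <- forcing_config(hindcast_years = 2000:2017,
                        projection_years = 2006:2040,
                        base_temp = 1.7, noise_sd = 0, zoop_noise_sd = 0,
                        cold_pool_pars = c(1, 1.2, 0),
                        scenarios = data.frame(scenario = "flat", rate = 0,
                                               bias = 0))
  f <- generate_forcing(cfg)
  expect_equal(unique(f$hindcast$indices$bottom_temp), 1.7)
  expect_equal(unique(f$flat$indices$bottom_temp), 1.7)
  expect_error(forcing_config(hindcast_years = integer(0)), "positive")
})

test_that("warming-rate tiers bracket the intended end-of-century warming", {
  cfg <- forcing_config(noise_sd = 0, zoop_noise_sd = 0,
                        cold_pool_pars = c(1, 1.2, 0))
  f <- generate_forcing(cfg)
  # end-of-century warming relative to the projection-period start (2018),
  # i.e. over roughly the next 80 years
  warming <- function(s) {
    t <- s$indices$bottom_temp
    t[s$years == 2100] - t[s$years == 2018]
  }
  # moderate-mitigation tier: ~1-2.5 C over the ~80-year projection span
  for (sc in c("rcp45_gcm1", "rcp45_gcm2", "rcp45_gcm3")) {
    expect_gt(warming(f[[sc]]), 1); expect_lt(warming(f[[sc]]), 2.5)
  }
  # high-baseline tier: ~2-4.5 C
  for (sc in c("rcp85_gcm1", "rcp85_gcm2", "rcp85_gcm3")) {
    expect_gt(warming(f[[sc]]), 2); expect_lt(warming(f[[sc]]), 4.5)
  }
})

test_that("generator is reproducible and its trend slope matches the configured rate", {
  cfg <- forcing_config(seed = 7L)
  expect_identical(generate_forcing(cfg), generate_forcing(cfg))
  cfg0 <- forcing_config(noise_sd = 0, zoop_noise_sd = 0,
                         cold_pool_pars = c(1, 1.2, 0))
  f <- generate_forcing(cfg0)
  s <- f$rcp85_gcm2
  slope <- unname(coef(lm(s$indices$bottom_temp ~ s$years))[2])
  expect_equal(slope, 0.042, tolerance = 1e-10)
  # zooplankton decreases with warming when the slope is negative
  expect_lt(cor(s$indices$zoop_fall, s$indices$bottom_temp), 0)
})

test_that("freeze_after holds a scenario's trend constant beyond the given year", {
  cfg <- forcing_config(noise_sd = 0, zoop_noise_sd = 0,
                        cold_pool_pars = c(1, 1.2, 0),
                        scenarios = data.frame(scenario = "frz", rate = 0.05,
                                               bias = 0, freeze_after = 2080L))
  f <- generate_forcing(cfg)
  t <- f$frz$indices$bottom_temp
  yrs <- f$frz$years
  expect_equal(length(unique(t[yrs >= 2080])), 1L)
  expect_gt(t[yrs == 2079], t[yrs == 2078])
})

test_that("bias correction reproduces the delta-method arithmetic", {
  # fut identical to hind: correction is the identity
  h <- climate_series("hind", 2000:2020,
                      list(bottom_temp = seq(1, 3, length.out = 21)))
  cfg <- bias_correction_config(2006, 2017)
  f <- h; f$scenario_id <- "fut"
  out <- bias_correct(f, h, cfg)
  expect_equal(out$indices$bottom_temp, h$indices$bottom_temp)

  # pure shift with equal SDs: the shift is removed
  f2 <- h; f2$scenario_id <- "shift"
  f2$indices$bottom_temp <- h$indices$bottom_temp + 3
  out2 <- bias_correct(f2, h, cfg)
  expect_equal(out2$indices$bottom_temp, h$indices$bottom_temp,
               tolerance = 1e-12)

  # hand-computed case with the sample-SD (n-1) convention:
  # hind ref {1,2,3}, fut ref {4,6,8}, fut value 10 -> 2 + (1/2)(10-6) = 4
  hy <- climate_series("h", 2001:2003, list(bottom_temp = c(1, 2, 3)))
  fy <- climate_series("f", 2001:2004, list(bottom_temp = c(4, 6, 8, 10)))
  c3 <- bias_correction_config(2001, 2003)
  out3 <- bias_correct(fy, hy, c3)
  expect_equal(out3$indices$bottom_temp[4], 4)
})

test_that("corrected projections match hindcast reference moments and the map is idempotent", {
  b <- cached_fixture(1)
  ref <- b$bc_cfg$ref_years
  h <- b$forcing$hindcast
  for (sc in c("rcp45_gcm1", "rcp85_gcm3")) {
    f <- b$forcing[[sc]]
    for (nm in setdiff(names(f$indices), "cold_pool")) {  # cold_pool may clip
      fr <- f$indices[[nm]][match(ref, f$years)]
      hr <- h$indices[[nm]][match(ref, h$years)]
      expect_equal(mean(fr), mean(hr), tolerance = 1e-10)
      expect_equal(sd(fr), sd(hr), tolerance = 1e-10)
    }
    again <- suppressWarnings(bias_correct(f, h, b$bc_cfg))
    for (nm in setdiff(names(f$indices), "cold_pool")) {
      expect_equal(again$indices[[nm]], f$indices[[nm]], tolerance = 1e-10)
    }
  }
})

test_that("degenerate reference variance and missing reference years are refused", {
  h <- climate_series("h", 2000:2020,
                      list(bottom_temp = seq(1, 3, length.out = 21)))
  flat <- climate_series("flat", 2000:2020,
                         list(bottom_temp = rep(2, 21)))
  cfg <- bias_correction_config(2006, 2017)
  expect_error(bias_correct(flat, h, cfg), "degenerate")
  # a constant (persistence-style) series is refused for the same reason:
  # its reference-period variance is zero and the variance ratio undefined
  short <- climate_series("s", 2010:2020,
                          list(bottom_temp = seq(1, 2, length.out = 11)))
  expect_error(bias_correct(short, h, cfg), "missing required years")
})

test_that("persistence scenario is constant at the hindcast reference mean", {
  b <- cached_fixture(1)
  h <- b$forcing$hindcast
  p <- make_persistence(h, b$bc_cfg, 2018:2100)
  ref_mean <- mean(h$indices$bottom_temp[match(b$bc_cfg$ref_years, h$years)])
  expect_true(is_constant_series(p))
  expect_equal(unique(p$indices$bottom_temp), ref_mean)
  expect_equal(var(p$indices$zoop_fall), 0)
  expect_error(make_persistence(h, b$bc_cfg, integer(0)), "empty")
})

test_that("forcing CSV round-trips", {
  b <- cached_fixture(1)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_forcing_csv(b$forcing[c("hindcast", "persistence")], tmp)
  back <- read_forcing_csv(tmp)
  expect_equal(back$persistence$indices$bottom_temp,
               b$forcing$persistence$indices$bottom_temp)
  expect_equal(back$hindcast$years, b$forcing$hindcast$years)
})

test_that("cold-pool bounds are enforced and clipping warns", {
  expect_error(climate_series("x", 2001:2002,
                              list(cold_pool = c(0.5, 1.4))), "0, 1")
  h <- climate_series("h", 2001:2010,
                      list(cold_pool = seq(0.1, 0.9, length.out = 10)))
  # near-constant over the reference years, then a large excursion: the
  # variance-ratio rescaling blows the excursion far outside [0, 1]
  f <- climate_series("f", 2001:2010,
                      list(cold_pool = c(0.49, 0.5, 0.51, 0.5, 0.5,
                                         0.99, 0.01, 0.5, 0.2, 0.9)))
  cfg <- bias_correction_config(2001, 2005)
  expect_warning(bias_correct(f, h, cfg), "clipped")
})
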