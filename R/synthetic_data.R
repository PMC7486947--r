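#' Study-emulation configuration for the synthetic fixture
#'
#' Defines the full set of "true" quantities from which every pipeline input
#' is generated: the climate-forcing generator settings (hindcast 1979-2017,
#' projections 2006-2100, six warming scenarios in two emission-like tiers),
#' three groundfish-like species (a pollock-like gadid, a cod-like gadid and
#' an arrowtooth-flounder-like flatfish) with age structure, selectivity,
#' maturity and thermal responses; true climate-enhanced recruitment
#' parameters (warming and zooplankton loss reduce gadid recruitment; the
#' flatfish is mildly warm-favoured); temperature-dependent predation pairs;
#' and true log-linear quota-system coefficients with correlated lognormal
#' noise for the 1992-2017 ABC/TAC/catch history.
#'
#' @param forcing A [forcing_config()]; its seed is overridden by the seed
#'   given to [make_study_fixture()].
#' @param quota_years Years of the synthetic quota history.
#' @return An object of class `study_config`. All elements can be modified
#'   before being passed to [make_study_fixture()].
#' @export
study_config <- function(forcing = forcing_config(),
                         quota_years = 1992:2017) {
  species <- list(
    species_config(
      name = "pollock", n_ages = 10,
      maturity = c(0, 0.1, 0.5, 0.9, rep(1, 6)),
      selectivity = c(0.05, 0.3, 0.7, 0.95, rep(1, 6)),
      M1 = c(0.9, 0.45, rep(0.3, 8)),
      w_base = c(0.05, 0.15, 0.30, 0.45, 0.60, 0.75, 0.88, 1.00, 1.10, 1.20),
      thermal_w_sens = -0.02, init_recruits = 3e7, hist_F = 0.3),
    species_config(
      name = "cod", n_ages = 12,
      maturity = c(0, 0, 0.1, 0.4, 0.8, rep(1, 7)),
      selectivity = c(0, 0.1, 0.4, 0.8, rep(1, 8)),
      M1 = c(0.7, 0.45, rep(0.37, 10)),
      w_base = c(0.2, 0.7, 1.4, 2.3, 3.3, 4.4, 5.5, 6.6, 7.6, 8.5, 9.3, 10),
      thermal_w_sens = -0.015, init_recruits = 8e5, hist_F = 0.3),
    species_config(
      name = "arrowtooth", n_ages = 12,
      maturity = c(0, 0, 0.05, 0.2, 0.5, 0.8, rep(1, 6)),
      selectivity = c(0, 0.05, 0.2, 0.5, 0.8, rep(1, 7)),
      M1 = c(0.4, 0.3, rep(0.2, 10)),
      w_base = c(0.05, 0.15, 0.3, 0.5, 0.75, 1.0, 1.3, 1.6, 1.9, 2.1, 2.3,
                 2.5),
      thermal_w_sens = -0.01, init_recruits = 6e5, hist_F = 0.05)
  )
  predation <- predation_config(list(
    list(predator = "cod", prey = "pollock", coef = 1e-7, temp_slope = 0.08,
         vuln = c(1, 0.6, 0.3, 0.1, rep(0, 6))),
    list(predator = "pollock", prey = "pollock", coef = 2e-8,
         temp_slope = 0.08, vuln = c(1, 0.5, 0.2, rep(0, 7))),
    list(predator = "arrowtooth", prey = "pollock", coef = 8e-8,
         temp_slope = 0.08, vuln = c(1, 0.7, 0.3, 0.1, rep(0, 6)))
  ))
  # true recruitment: alpha_eff is the intercept at baseline covariate
  # values; the raw alpha is derived inside make_study_fixture once the
  # hindcast baseline is known
  recruit_true <- list(
    pollock = list(alpha_eff = 2.2, beta0 = 6e-8,
                   betas = c(bottom_temp = -0.25, cold_pool = 0.6,
                             zoop_spring = 0.06, zoop_fall = 0.10),
                   sigma = 0.5, ssb_typ = 5e6),
    cod = list(alpha_eff = 1.4, beta0 = 2e-6,
               betas = c(bottom_temp = -0.20, cold_pool = 0.4,
                         zoop_spring = 0.05, zoop_fall = 0.08),
               sigma = 0.45, ssb_typ = 1e6),
    arrowtooth = list(alpha_eff = 1.0, beta0 = 2.6e-6,
                      betas = c(bottom_temp = 0.05, cold_pool = -0.2,
                                zoop_spring = 0.02, zoop_fall = 0.02),
                      sigma = 0.35, ssb_typ = 6e5)
  )
  quota_true <- list(
    abc_typ = c(pollock = 1.4e6, cod = 3e5, arrowtooth = 1.5e5),
    abc_sd_log = 0.25,
    tac_ratio = c(pollock = 0.85, cod = 0.9, arrowtooth = 0.6),
    tac_beta = c(pollock = 0.95, cod = 1.0, arrowtooth = 1.0),
    tac_gamma = list(pollock = c(cod = -1e-7),
                     cod = c(pollock = -2e-8), arrowtooth = NULL),
    tac_theta = list(pollock = c(a80 = -0.05, afa = 0.08),
                     cod = c(a80 = 0.05, afa = 0), arrowtooth = c(a80 = 0.1,
                                                                  afa = 0)),
    catch_ratio = c(pollock = 0.97, cod = 0.9, arrowtooth = 0.5),
    catch_beta = c(pollock = 1.0, cod = 1.0, arrowtooth = 1.0),
    catch_theta = list(pollock = c(a80 = 0, afa = 0.03),
                       cod = c(a80 = 0, afa = 0),
                       arrowtooth = c(a80 = -0.05, afa = 0)),
    sd_tac = 0.08, sd_catch = 0.10,
    resid_cor = matrix(c(1, 0.5, 0.2,
                         0.5, 1, 0.2,
                         0.2, 0.2, 1), 3, 3,
                       dimnames = list(c("pollock", "cod", "arrowtooth"),
                                       c("pollock", "cod", "arrowtooth")))
  )
  structure(list(forcing = forcing, species = species,
                 predation = predation, recruit_true = recruit_true,
                 quota_true = quota_true,
                 quota_years = as.integer(quota_years)),
            class = "study_config")
}

#' Generate a synthetic ABC/TAC/catch history
#'
#' Draws annual ABCs (iid lognormal around species-typical levels), builds
#' 0/1 policy indicator columns (`afa` switching on in 1999, `a80` in 2008),
#' then generates TAC from the true log-linear TAC model and catch from the
#' true log-linear catch model, with contemporaneous cross-species
#' correlation in the lognormal errors. Management constraints are enforced
#' on the generated data (TAC <= ABC, catch <= TAC).
#'
#' @param cfg A [study_config()] (its `quota_true` block is the truth).
#' @param seed Integer RNG seed.
#' @param years Override of `cfg$quota_years`.
#' @return Long data frame: `year`, `species`, `abc`, `tac`, `catch`,
#'   `a80`, `afa`.
#' @export
make_quota_history <- function(cfg = study_config(), seed = 1L,
                               years = cfg$quota_years) {
  qt <- cfg$quota_true
  spp <- names(qt$abc_typ)
  n <- length(years)
  set.seed(as.integer(seed))
  abc <- sapply(spp, function(sp) {
    qt$abc_typ[[sp]] * exp(stats::rnorm(n, 0, qt$abc_sd_log))
  })
  ind <- data.frame(afa = as.numeric(years >= 1999),
                    a80 = as.numeric(years >= 2008))
  Sig_t <- qt$sd_tac^2 * qt$resid_cor[spp, spp]
  Sig_c <- qt$sd_catch^2 * qt$resid_cor[spp, spp]
  e_tac <- MASS::mvrnorm(n, rep(0, length(spp)), Sig_t)
  e_cat <- MASS::mvrnorm(n, rep(0, length(spp)), Sig_c)
  colnames(e_tac) <- colnames(e_cat) <- spp

  lin <- function(sp, driver_own, driver_all, beta, ratio, gamma, theta) {
    a <- log(ratio[[sp]]) + (1 - beta[[sp]]) * log(qt$abc_typ[[sp]])
    lp <- a + beta[[sp]] * log(driver_own)
    for (o in names(gamma[[sp]])) lp <- lp + gamma[[sp]][[o]] * driver_all[, o]
    for (k in names(theta[[sp]])) lp <- lp + theta[[sp]][[k]] * ind[[k]]
    lp
  }
  tac <- sapply(spp, function(sp) {
    pmin(exp(lin(sp, abc[, sp], abc, qt$tac_beta, qt$tac_ratio, qt$tac_gamma,
                 qt$tac_theta) + e_tac[, sp]), abc[, sp])
  })
  catch <- sapply(spp, function(sp) {
    gamma0 <- stats::setNames(vector("list", length(spp)), spp)  # no cross terms
    pmin(exp(lin(sp, tac[, sp], tac, qt$catch_beta, qt$catch_ratio, gamma0,
                 qt$catch_theta) + e_cat[, sp]), tac[, sp])
  })
  do.call(rbind, lapply(seq_along(spp), function(i) {
    data.frame(year = years, species = spp[i], abc = abc[, i],
               tac = tac[, i], catch = catch[, i],
               a80 = ind$a80, afa = ind$afa, row.names = NULL)
  }))
}

#' Build the complete synthetic study fixture
#'
#' Produces every input the pipeline consumes, with the statistical structure
#' the downstream analyses assume: bias-corrected multi-GCM-like climate
#' forcing plus the persistence scenario; per-species recruitment
#' observations generated exactly from the true climate-enhanced Ricker
#' model under hindcast covariates; the quota history from the true
#' log-linear catch functions; and the configured operating model. A fixed
#' seed yields byte-identical output.
#'
#' @param cfg A [study_config()].
#' @param seed Integer master seed (sub-seeds are derived deterministically).
#' @param recruit_noise Scale on the recruitment observation noise (1 =
#'   configured sigmas; 0 = noiseless observations that refit exactly).
#' @param out_dir Optional directory; when given, forcing, recruitment
#'   observations and quota history are written as CSV with a small
#'   manifest.
#' @return List with elements `forcing_raw` (uncorrected), `forcing`
#'   (named list: `hindcast`, bias-corrected projections, `persistence`),
#'   `om` ([om_config()]), `recruit_true` (named list of `recruit_model`),
#'   `recruit_obs` (named list of data frames), `quota_history`, `bc_cfg`,
#'   `projection_years`, `ref_temp` and `cfg`.
#' @export
make_study_fixture <- function(cfg = study_config(), seed = 1L,
                               recruit_noise = 1, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  seed <- as.integer(seed)
  bc <- bias_correction_config()
  fc <- cfg$forcing
  fc$seed <- seed
  raw <- generate_forcing(fc)
  hind <- raw$hindcast
  corrected <- lapply(raw[-1L], bias_correct, hind = hind, cfg = bc)
  projection_years <- fc$projection_years
  persistence <- make_persistence(hind, bc, projection_years)
  forcing <- c(list(hindcast = hind), corrected,
               list(persistence = persistence))

  ref_temp <- mean(hind$indices$bottom_temp[match(bc$ref_years, hind$years)])
  om <- om_config(cfg$species, cfg$predation, ref_temp = ref_temp)

  # baseline covariate values at which alpha_eff is anchored
  i_ref <- match(bc$ref_years, hind$years)
  x_base <- vapply(hind$indices, function(v) mean(v[i_ref]), numeric(1))
  recruit_true <- lapply(cfg$recruit_true, function(rt) {
    alpha <- rt$alpha_eff - sum(rt$betas * x_base[names(rt$betas)])
    recruit_model(alpha = alpha, beta0 = rt$beta0, betas = rt$betas,
                  sigma = rt$sigma)
  })

  # recruitment observations on the hindcast years, generated from the truth
  set.seed(seed + 1000L)
  obs_years <- hind$years[-1L]
  recruit_obs <- lapply(names(recruit_true), function(sp) {
    rt <- cfg$recruit_true[[sp]]
    m <- recruit_true[[sp]]
    n <- length(obs_years)
    ssb <- rt$ssb_typ * exp(stats::rnorm(n, 0, 0.3))
    i <- match(obs_years, hind$years)
    X <- data.frame(lapply(hind$indices, `[`, i))
    eps <- stats::rnorm(n, 0, m$sigma * recruit_noise)
    R <- vapply(seq_len(n), function(j) {
      predict_recruitment(m, ssb[j], X[j, ], eps[j])
    }, numeric(1))
    cbind(data.frame(year = obs_years, ssb = ssb, recruits = R), X)
  })
  names(recruit_obs) <- names(recruit_true)

  quota_history <- make_quota_history(cfg, seed = seed + 2000L)

  bundle <- list(forcing_raw = raw, forcing = forcing, om = om,
                 recruit_true = recruit_true, recruit_obs = recruit_obs,
                 quota_history = quota_history, bc_cfg = bc,
                 projection_years = projection_years, ref_temp = ref_temp,
                 cfg = cfg, seed = seed)
  if (!is.null(out_dir)) .write_fixture(bundle, out_dir)
  bundle
}

.write_fixture <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_forcing_csv(bundle$forcing, file.path(out_dir, "forcing.csv"))
  obs <- do.call(rbind, lapply(names(bundle$recruit_obs), function(sp) {
    cbind(species = sp, bundle$recruit_obs[[sp]])
  }))
  utils::write.csv(obs, file.path(out_dir, "recruit_obs.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$quota_history,
                   file.path(out_dir, "quota_history.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = bundle$seed,
    ref_temp = bundle$ref_temp,
    ref_years = range(bundle$bc_cfg$ref_years),
    projection_years = range(bundle$projection_years),
    species = names(bundle$om$species),
    files = c("forcing.csv", "recruit_obs.csv", "quota_history.csv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yml"))
  } else {
    utils::write.csv(data.frame(key = names(unlist(manifest)),
                                value = unlist(manifest)),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Fit all study inputs from a fixture bundle
#'
#' Convenience wrapper: fits the climate-enhanced recruitment model to each
#' species' observations and the catch-function ensemble to the quota
#' history.
#'
#' @param bundle Output of [make_study_fixture()].
#' @param ... Passed to [fit_catch_functions()].
#' @return List with `recruit_fit` (named list of `recruit_model`) and
#'   `catch_model`.
#' @export
fit_study_inputs <- function(bundle, ...) {
  recruit_fit <- lapply(bundle$recruit_obs, fit_recruitment)
  catch_model <- fit_catch_functions(bundle$quota_history,
                                     indicators = c("a80", "afa"), ...)
  list(recruit_fit = recruit_fit, catch_model = catch_model)
}

#' Tiny three-species worked example
#'
#' A 3-species, 5-age, 10-year bundle with round printed-in-config
#' parameters, small enough that every intermediate number can be recomputed
#' by hand or by an independent plain-loop oracle: constant-trend forcing,
#' covariate-light recruitment (temperature effect only, no process error)
#' and a fixed fishing-mortality vector.
#'
#' @return List with `om`, `forcing` (2001-2010), `recruit_models`,
#'   `F` (named vector) and `years`.
#' @export
make_toy_worked_example <- function() {
  mk <- function(name, M1, w_scale, init_recruits) {
    species_config(
      name = name, n_ages = 5,
      maturity = c(0, 0.5, 1, 1, 1),
      selectivity = c(0.2, 0.6, 1, 1, 1),
      M1 = rep(M1, 5),
      w_base = w_scale * c(0.1, 0.3, 0.6, 0.9, 1.2),
      thermal_w_sens = -0.02, init_recruits = init_recruits, hist_F = 0.1)
  }
  species <- list(mk("toy_a", 0.3, 1.0, 1000),
                  mk("toy_b", 0.4, 2.0, 400),
                  mk("toy_c", 0.2, 0.5, 600))
  predation <- predation_config(list(
    list(predator = "toy_b", prey = "toy_a", coef = 1e-4, temp_slope = 0.1,
         vuln = c(1, 0.5, 0, 0, 0))))
  om <- om_config(species, predation, ref_temp = 2.0)
  years <- 2001:2010
  forcing <- climate_series("toy", years, list(
    bottom_temp = seq(2.0, 2.45, by = 0.05),
    cold_pool = rep(0.3, 10),
    zoop_spring = rep(4, 10),
    zoop_fall = rep(3, 10)))
  recruit_models <- list(
    toy_a = recruit_model(alpha = 1.0, beta0 = 1e-3,
                          betas = c(bottom_temp = -0.2), sigma = 0),
    toy_b = recruit_model(alpha = 0.8, beta0 = 8e-4,
                          betas = c(bottom_temp = -0.1), sigma = 0),
    toy_c = recruit_model(alpha = 0.6, beta0 = 1.2e-3,
                          betas = c(bottom_temp = 0.05), sigma = 0))
  list(om = om, forcing = forcing, recruit_models = recruit_models,
       F = c(toy_a = 0.2, toy_b = 0.1, toy_c = 0.05), years = years)
}
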