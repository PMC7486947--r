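#' Biological configuration for one species
#'
#' Age-structured life-history and fishery parameters for a single stock.
#' Units convention used throughout the operating model: numbers-at-age in
#' thousands of fish, weight-at-age in kg, so `sum(N * W)` is biomass in
#' metric tons.
#'
#' @param name Species label (must match the names used in recruitment models,
#'   predation pairs and quota histories).
#' @param n_ages Number of modeled ages (>= 2); the oldest age is a plus
#'   group.
#' @param maturity Proportion mature at age, in [0, 1], length `n_ages`.
#' @param selectivity Average fishery selectivity at age, in [0, 1].
#' @param M1 Residual (non-predation) natural mortality at age (per year).
#' @param w_base Baseline weight-at-age (kg) at zero temperature anomaly.
#' @param thermal_w_sens Fractional change in weight per deg C of bottom
#'   temperature anomaly (negative: warming reduces size-at-age).
#' @param w_floor_frac Lower clamp on the thermal weight multiplier (fraction
#'   of baseline, > 0).
#' @param init_recruits Age-1 numbers (thousands) used to seed the initial
#'   equilibrium age structure.
#' @param hist_F Historical average fishing mortality (per year); used as the
#'   fixed rate for species whose target-F is solved in the second phase.
#' @return An object of class `species_config`.
#' @export
species_config <- function(name, n_ages, maturity, selectivity, M1, w_base,
                           thermal_w_sens = -0.02, w_floor_frac = 0.1,
                           init_recruits = 1e6, hist_F = 0.1) {
  n_ages <- as.integer(n_ages)
  stopifnot(n_ages >= 2L,
            length(maturity) == n_ages, length(selectivity) == n_ages,
            length(M1) == n_ages, length(w_base) == n_ages,
            all(maturity >= 0 & maturity <= 1),
            all(selectivity >= 0 & selectivity <= 1),
            all(M1 >= 0), all(w_base > 0),
            w_floor_frac > 0, init_recruits > 0, hist_F >= 0)
  structure(list(name = name, n_ages = n_ages, maturity = maturity,
                 selectivity = selectivity, M1 = M1, w_base = w_base,
                 thermal_w_sens = thermal_w_sens,
                 w_floor_frac = w_floor_frac,
                 init_recruits = init_recruits, hist_F = hist_F),
            class = "species_config")
}

#' Simplified temperature-dependent predation configuration
#'
#' Each row of `pairs` defines one predator-prey interaction. Prey predation
#' mortality at age is
#' `M2_{prey,a} = sum_pred coef * vuln_a * B_pred * exp(temp_slope * anomaly)`:
#' linear in predator biomass, scaled by a prey-age vulnerability, and
#' (by default) increasing with temperature. A transparent stand-in for a
#' bioenergetics predation sub-model, exposed entirely through configuration.
#'
#' @param pairs List of lists with elements `predator`, `prey`, `coef`
#'   (per year per ton of predator biomass, >= 0), `temp_slope` (per deg C),
#'   and `vuln` (vulnerability at prey age, values in [0, 1]; recycled to the
#'   prey's age range).
#' @return An object of class `predation_config`. An empty `pairs` list means
#'   no predation (M2 = 0).
#' @export
predation_config <- function(pairs = list()) {
  for (p in pairs) {
    stopifnot(all(c("predator", "prey", "coef", "temp_slope", "vuln")
                  %in% names(p)),
              p$coef >= 0, all(p$vuln >= 0 & p$vuln <= 1))
  }
  structure(list(pairs = pairs), class = "predation_config")
}

#' Bundle an operating model: species, predation and the thermal reference
#'
#' @param species List of [species_config()] objects (names taken from the
#'   configs).
#' @param predation A [predation_config()] (default: none).
#' @param ref_temp Reference bottom temperature (deg C) defining the zero
#'   anomaly for growth and predation responses; conventionally the hindcast
#'   reference-period mean.
#' @return An object of class `om_config`.
#' @export
om_config <- function(species, predation = predation_config(),
                      ref_temp = 0) {
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "species_config")))
  names(species) <- vapply(species, `[[`, character(1), "name")
  for (p in predation$pairs) {
    if (!all(c(p$predator, p$prey) %in% names(species))) {
      stop(sprintf("om_config: unknown species pair %s -> %s",
                   p$predator, p$prey))
    }
  }
  structure(list(species = species, predation = predation,
                 ref_temp = ref_temp),
            class = "om_config")
}

#' Temperature-adjusted weight-at-age
#'
#' Multiplicative-linear thermal response `g(anomaly) = 1 + sens * anomaly`,
#' clamped below at `w_floor_frac` (clamps raise a warning). `g(0) = 1`
#' exactly.
#'
#' @param cfg A [species_config()].
#' @param temp_anomaly Bottom-temperature anomaly (deg C) relative to the
#'   operating model's reference temperature.
#' @return Weight-at-age vector (kg), strictly positive.
#' @export
weight_at_age <- function(cfg, temp_anomaly) {
  stopifnot(inherits(cfg, "species_config"), is.finite(temp_anomaly))
  g <- 1 + cfg$thermal_w_sens * temp_anomaly
  if (g < cfg$w_floor_frac) {
    warning(sprintf(
      "weight_at_age(%s): thermal multiplier %.3f clamped to floor %.3f",
      cfg$name, g, cfg$w_floor_frac))
    g <- cfg$w_floor_frac
  }
  cfg$w_base * g
}

#' Predation mortality at age for every species
#'
#' @param pred_cfg A [predation_config()].
#' @param biomass Named vector of current total biomass (tons) per species.
#' @param om The [om_config()] (for age ranges).
#' @param temp_anomaly Bottom-temperature anomaly (deg C).
#' @return Named list of M2-at-age vectors (per year), zero where no
#'   predator is configured.
#' @export
predation_mortality <- function(pred_cfg, biomass, om, temp_anomaly = 0) {
  stopifnot(inherits(pred_cfg, "predation_config"), inherits(om, "om_config"))
  M2 <- lapply(om$species, function(s) rep(0, s$n_ages))
  for (p in pred_cfg$pairs) {
    if (!all(c(p$predator, p$prey) %in% names(om$species))) {
      stop(sprintf("predation_mortality: unknown species pair %s -> %s",
                   p$predator, p$prey))
    }
    vuln <- rep_len(p$vuln, om$species[[p$prey]]$n_ages)
    M2[[p$prey]] <- M2[[p$prey]] +
      p$coef * vuln * biomass[[p$predator]] * exp(p$temp_slope * temp_anomaly)
  }
  M2
}

#' Baranov catch equation
#'
#' `catch = sum_a (S_a * F / Z_a) * (1 - exp(-Z_a)) * N_a * W_a`. The result
#' is in `N * W` units (tons under the package convention of thousands of
#' fish times kg).
#'
#' @param N,W,S Numbers, weight and selectivity at age (equal lengths).
#' @param F Fully-selected fishing mortality (scalar, >= 0).
#' @param Z Total mortality at age (`M1 + M2 + S * F`), must be > 0 wherever
#'   `S * F > 0`.
#' @return Catch biomass (scalar). Exactly 0 when `F = 0`.
#' @export
baranov_catch <- function(N, W, S, F, Z) {
  stopifnot(length(N) == length(W), length(N) == length(S),
            length(N) == length(Z), F >= 0, all(N >= 0), all(W >= 0))
  if (F == 0) return(0)
  active <- S * F > 0
  if (any(active & Z <= 0)) {
    stop("baranov_catch: Z = 0 at an age with positive fishing mortality")
  }
  idx <- active & N > 0
  sum((S[idx] * F / Z[idx]) * (1 - exp(-Z[idx])) * N[idx] * W[idx])
}

# Build a full population state for one year: realized weights, predation
# and natural mortality at age, spawning biomass. N is a named list of
# numbers-at-age (thousands).
.make_state <- function(om, year, N, climate_row) {
  anomaly <- climate_row[["bottom_temp"]] - om$ref_temp
  W <- lapply(om$species, function(s) weight_at_age(s, anomaly))
  biomass <- vapply(names(om$species),
                    function(sp) sum(N[[sp]] * W[[sp]]), numeric(1))
  M2 <- predation_mortality(om$predation, biomass, om, anomaly)
  M <- lapply(names(om$species),
              function(sp) om$species[[sp]]$M1 + M2[[sp]])
  names(M) <- names(om$species)
  ssb <- vapply(names(om$species), function(sp) {
    sum(om$species[[sp]]$maturity * N[[sp]] * W[[sp]])
  }, numeric(1))
  structure(list(year = year, N = N, W = W, M = M, M2 = M2,
                 biomass = biomass, ssb = ssb,
                 temp_anomaly = anomaly,
                 bottom_temp = climate_row[["bottom_temp"]]),
            class = "pop_state")
}

#' @export
print.pop_state <- function(x, ...) {
  cat(sprintf("<pop_state> year %d; SSB (t): %s\n", x$year,
              paste(sprintf("%s=%.0f", names(x$ssb), x$ssb), collapse = ", ")))
  invisible(x)
}

.climate_row <- function(forcing, year) {
  i <- match(year, forcing$years)
  if (is.na(i)) {
    stop(sprintf("forcing scenario '%s' does not cover year %d",
                 forcing$scenario_id, year))
  }
  vapply(forcing$indices, `[`, numeric(1), i)
}

#' Initialize a population at (unfished, zero-anomaly) equilibrium structure
#'
#' Age structure from constant recruitment `init_recruits` surviving residual
#' mortality `M1`, with the plus group accumulating survivors geometrically.
#'
#' @param om An [om_config()].
#' @param forcing A `climate_series` covering `year`.
#' @param year First simulation year.
#' @return A `pop_state`.
#' @export
init_population <- function(om, forcing, year) {
  stopifnot(inherits(om, "om_config"), inherits(forcing, "climate_series"))
  N <- lapply(om$species, function(s) {
    surv <- exp(-s$M1)
    n <- numeric(s$n_ages)
    n[1L] <- s$init_recruits
    for (a in 2:s$n_ages) n[a] <- n[a - 1L] * surv[a - 1L]
    # plus group: geometric accumulation at the oldest-age survival
    sA <- surv[s$n_ages]
    if (sA < 1) n[s$n_ages] <- n[s$n_ages] / (1 - sA)
    n
  })
  .make_state(om, as.integer(year), N, .climate_row(forcing, year))
}

#' Advance the population one year
#'
#' Applies total mortality `Z = M1 + M2 + S * F` through year `y-1` (the
#' state's year), moves survivors up an age (the oldest age accumulating as a
#' plus group), and injects recruitment at age 1 computed from the state's
#' spawning biomass `B_{y-1}` and year-`y` covariates (plus a log-scale
#' process-error deviate). Year-`y` weights, predation mortality and spawning
#' biomass are then recomputed from the new numbers and year-`y` climate.
#'
#' @param state Current `pop_state` (year `y-1`).
#' @param om An [om_config()].
#' @param forcing `climate_series` covering year `y = state$year + 1`.
#' @param recruit_models Named list of `recruit_model`s, one per species.
#' @param F Named vector of fishing mortality applied during year `y-1`
#'   (default all zero).
#' @param eps Named vector of log-scale recruitment deviates for year `y`
#'   (default all zero).
#' @return The year-`y` `pop_state`, with attribute `"F_applied"`.
#' @export
advance_year <- function(state, om, forcing, recruit_models,
                         F = NULL, eps = NULL) {
  stopifnot(inherits(state, "pop_state"), inherits(om, "om_config"))
  spp <- names(om$species)
  if (is.null(F)) F <- stats::setNames(rep(0, length(spp)), spp)
  if (is.null(eps)) eps <- stats::setNames(rep(0, length(spp)), spp)
  stopifnot(all(F >= 0))
  year_next <- state$year + 1L
  clim_next <- .climate_row(forcing, year_next)
  N_next <- list()
  for (sp in spp) {
    s <- om$species[[sp]]
    Z <- state$M[[sp]] + s$selectivity * F[[sp]]
    surv <- state$N[[sp]] * exp(-Z)
    n <- numeric(s$n_ages)
    n[2:s$n_ages] <- surv[1:(s$n_ages - 1L)]
    n[s$n_ages] <- n[s$n_ages] + surv[s$n_ages]  # plus group
    R <- predict_recruitment(recruit_models[[sp]], state$ssb[[sp]],
                             X = clim_next, eps = eps[[sp]])
    n[1L] <- R
    if (any(n < 0)) stop("advance_year: negative abundance (internal error)")
    N_next[[sp]] <- n
  }
  out <- .make_state(om, year_next, N_next, clim_next)
  attr(out, "F_applied") <- F
  out
}

#' Solve the effective fishing mortality that yields a target catch
#'
#' Bracketed root finding of `baranov_catch(N, W, S, F, M + S * F) = target`
#' on `[0, F_max]`. If the target exceeds the catch attainable at `F_max`,
#' `F_max` is returned with a warning reporting the shortfall.
#'
#' @param N,W,S,M Numbers, weight, selectivity and natural mortality at age.
#' @param target_catch Target catch in `N * W` units (tons), >= 0.
#' @param F_max Upper bracket for F (per year).
#' @param tol Relative tolerance on the achieved catch.
#' @return Effective F (scalar). 0 for a zero target.
#' @export
solve_F_from_catch <- function(N, W, S, M, target_catch, F_max = 5,
                               tol = 1e-8) {
  stopifnot(target_catch >= 0, F_max > 0)
  if (target_catch == 0) return(0)
  f_of <- function(F) baranov_catch(N, W, S, F, M + S * F) - target_catch
  c_max <- baranov_catch(N, W, S, F_max, M + S * F_max)
  if (c_max <= 0) {
    warning("solve_F_from_catch: no exploitable biomass; returning F = 0")
    return(0)
  }
  if (target_catch >= c_max) {
    if (target_catch > c_max * (1 + 1e-12)) {
      warning(sprintf(
        "solve_F_from_catch: target %.6g exceeds attainable %.6g; applying F_max = %g (shortfall %.6g)",
        target_catch, c_max, F_max, target_catch - c_max))
    }
    return(F_max)
  }
  stats::uniroot(f_of, c(0, F_max), tol = tol * max(1, F_max) * 1e-4)$root
}

# Generic annual projection engine. `controller(state)` returns a list with
# at least `F` (named vector applied during the state's year) and optionally
# `abc`, `tac`, `catch` (named vectors, tons) for the record. Recruitment
# deviates `eps_mat` is a years x species matrix (rownames = years), applied
# to the recruitment entering that year.
.run_projection <- function(om, recruit_models, forcing, years, controller,
                            eps_mat = NULL, init_state = NULL) {
  years <- as.integer(years)
  spp <- names(om$species)
  state <- if (is.null(init_state)) {
    init_population(om, forcing, years[1L])
  } else init_state
  stopifnot(state$year == years[1L])
  zero <- stats::setNames(rep(0, length(spp)), spp)
  eps_for <- function(y) {
    if (is.null(eps_mat)) return(zero)
    eps_mat[as.character(y), spp]
  }
  rows <- vector("list", length(years))
  recruits <- vapply(spp, function(sp) state$N[[sp]][1L], numeric(1))
  for (k in seq_along(years)) {
    y <- years[k]
    ctl <- controller(state)
    realized_catch <- vapply(spp, function(sp) {
      s <- om$species[[sp]]
      baranov_catch(state$N[[sp]], state$W[[sp]], s$selectivity,
                    ctl$F[[sp]], state$M[[sp]] + s$selectivity * ctl$F[[sp]])
    }, numeric(1))
    rows[[k]] <- data.frame(
      year = y, species = spp,
      recruits = unname(recruits),
      ssb = unname(state$ssb[spp]),
      abc = if (is.null(ctl$abc)) NA_real_ else unname(ctl$abc[spp]),
      tac = if (is.null(ctl$tac)) NA_real_ else unname(ctl$tac[spp]),
      catch = unname(realized_catch),
      F = unname(ctl$F[spp]),
      bottom_temp = state$bottom_temp,
      row.names = NULL
    )
    if (k < length(years)) {
      state <- advance_year(state, om, forcing, recruit_models,
                            F = ctl$F, eps = eps_for(years[k + 1L]))
      if (any(!is.finite(unlist(state$N)))) {
        stop(sprintf("projection: non-finite abundance entering year %d", state$year))
      }
      recruits <- vapply(spp, function(sp) state$N[[sp]][1L], numeric(1))
    }
  }
  list(table = do.call(rbind, rows), final_state = state)
}

# Constant-F projection (deterministic unless eps_mat given).
.project_fixed_F <- function(om, recruit_models, forcing, years, F,
                             eps_mat = NULL) {
  spp <- names(om$species)
  F <- stats::setNames(rep_len(F, length(spp)), spp)[spp]
  controller <- function(state) list(F = F)
  .run_projection(om, recruit_models, forcing, years, controller, eps_mat)
}

#' Project the unfished population and derive B0
#'
#' Runs the operating model forward with `F = 0` in every year (no process
#' error) and returns the spawning-biomass trajectories together with the
#' unfished reference biomass `B0`, the mean SSB over the final reference
#' window (default the last five projection years, the 2095-2099 convention).
#'
#' @param om An [om_config()].
#' @param recruit_models Named list of `recruit_model`s.
#' @param forcing `climate_series` covering `years` (conventionally the
#'   persistence scenario; reference points are climate-naive).
#' @param years Projection years.
#' @param window Length-2 year range over which B0 is averaged; default the
#'   final five years.
#' @return List with `ssb` (years x species matrix), `table` (long data
#'   frame) and `B0` (named vector, tons).
#' @export
project_unfished <- function(om, recruit_models, forcing, years,
                             window = NULL) {
  years <- as.integer(years)
  if (is.null(window)) window <- c(years[length(years)] - 4L,
                                   years[length(years)])
  if (window[1L] < years[1L] || window[2L] > years[length(years)]) {
    stop("project_unfished: B0 window outside the projection range")
  }
  res <- .project_fixed_F(om, recruit_models, forcing, years, 0)
  tab <- res$table
  ssb <- do.call(cbind, lapply(names(om$species), function(sp) {
    tab$ssb[tab$species == sp]
  }))
  dimnames(ssb) <- list(years, names(om$species))
  in_win <- years >= window[1L] & years <= window[2L]
  B0 <- colMeans(ssb[in_win, , drop = FALSE])
  list(ssb = ssb, table = tab, B0 = B0, window = window)
}
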