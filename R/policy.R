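#' Harvest policy: climate-naive reference points, sloping HCR, catch cap
#'
#' @param B0 Named vector of unfished spawning biomass (tons) per species,
#'   from [project_unfished()] under the persistence scenario.
#' @param F_target Named vector of target fishing mortality (per year) that
#'   drives end-window depletion to `target_frac` of B0 under persistence.
#' @param cutoff_frac Fraction of B0 below which the fishery closes
#'   (default 0.20, the ecosystem cutoff B20%).
#' @param target_frac Fraction of B0 defining the target biomass B40%
#'   (default 0.40).
#' @param cap Ecosystem-level cap on summed TAC (tons; default 2,000,000).
#' @param window Reference year window used when the reference points were
#'   derived (informational).
#' @param ramp Shape of the control rule between the cutoff and the target:
#'   `"linear"` (straight line from (0.20 B0, 0) to (0.40 B0, F_target),
#'   the default) or `"tier3"` (the NPFMC Tier-3 form
#'   `F_target * (B/B40 - a) / (1 - a)` with `a = cutoff_frac/target_frac`,
#'   which coincides with the same endpoints for this cutoff/target pair).
#' @return An object of class `harvest_policy`.
#' @export
harvest_policy <- function(B0, F_target, cutoff_frac = 0.20,
                           target_frac = 0.40, cap = 2e6,
                           window = c(2095L, 2099L),
                           ramp = c("linear", "tier3")) {
  ramp <- match.arg(ramp)
  stopifnot(!is.null(names(B0)), !is.null(names(F_target)),
            all(names(F_target) %in% names(B0)),
            all(B0 > 0), all(F_target >= 0),
            cutoff_frac > 0, cutoff_frac < target_frac, target_frac <= 1,
            cap > 0)
  structure(list(B0 = B0, F_target = F_target,
                 cutoff_frac = cutoff_frac, target_frac = target_frac,
                 cap = cap, window = window, ramp = ramp),
            class = "harvest_policy")
}

#' @export
print.harvest_policy <- function(x, ...) {
  cat(sprintf("<harvest_policy> cutoff %.0f%% B0, target %.0f%% B0, cap %.3g t, ramp '%s'\n",
              100 * x$cutoff_frac, 100 * x$target_frac, x$cap, x$ramp))
  for (sp in names(x$B0)) {
    cat(sprintf("  %s: B0 = %.0f t, F_target = %.4f\n", sp, x$B0[[sp]],
                x$F_target[[sp]]))
  }
  invisible(x)
}

#' Tier-3 sloping harvest control rule with ecosystem cutoff
#'
#' Returns the control-rule fishing mortality given start-of-year spawning
#' biomass: `F_target` at or above the target biomass (40% of B0), 0 below
#' the cutoff (20% of B0), and a continuous sloping ramp in between.
#'
#' @param policy A [harvest_policy()].
#' @param B_now Current spawning biomass (tons, >= 0); vectorized.
#' @param species Species name (to select B0 and F_target).
#' @return F_ABC (per year), in `[0, F_target]`, monotone non-decreasing in
#'   `B_now`.
#' @export
sloping_hcr <- function(policy, B_now, species) {
  stopifnot(inherits(policy, "harvest_policy"), all(B_now >= 0),
            species %in% names(policy$B0))
  B0 <- policy$B0[[species]]
  Ft <- policy$F_target[[species]]
  dep <- B_now / B0
  lo <- policy$cutoff_frac
  hi <- policy$target_frac
  frac <- if (policy$ramp == "linear") {
    (dep - lo) / (hi - lo)
  } else {
    a <- lo / hi
    (dep / hi - a) / (1 - a)
  }
  Ft * pmin(pmax(frac, 0), 1)
}

#' Acceptable biological catch from the control-rule F
#'
#' Baranov catch at `F_ABC` with total mortality `Z = M1 + M2 + S * F_ABC`
#' from the current year's state, summed over ages, per species.
#'
#' @param state A `pop_state`.
#' @param om An [om_config()].
#' @param F_ABC Named vector of control-rule fishing mortalities.
#' @return Named vector of ABC (tons); zero exactly where `F_ABC` is zero.
#' @export
compute_abc <- function(state, om, F_ABC) {
  stopifnot(inherits(state, "pop_state"), inherits(om, "om_config"))
  vapply(names(om$species), function(sp) {
    s <- om$species[[sp]]
    baranov_catch(state$N[[sp]], state$W[[sp]], s$selectivity, F_ABC[[sp]],
                  state$M[[sp]] + s$selectivity * F_ABC[[sp]])
  }, numeric(1))
}

# End-window mean depletion (mean SSB over window / B0) for a constant-F
# projection under the given (persistence) forcing, deterministic.
.depletion_at_F <- function(om, recruit_models, forcing, years, window, B0,
                            F) {
  res <- .project_fixed_F(om, recruit_models, forcing, years, F)
  tab <- res$table
  in_win <- tab$year >= window[1L] & tab$year <= window[2L]
  vapply(names(om$species), function(sp) {
    mean(tab$ssb[in_win & tab$species == sp]) / B0[[sp]]
  }, numeric(1))
}

#' Iteratively solve climate-naive target fishing mortalities
#'
#' Two-phase iterative procedure under the persistence scenario (the solver
#' refuses non-constant forcing; reference points are climate-naive by
#' construction):
#' \enumerate{
#'   \item jointly solve the gadids' (`joint_species`) F such that each
#'     species' mean spawning biomass over the reference window equals
#'     `target_frac * B0`, holding the remaining species at their
#'     historical-average F (`hist_F` in their configs);
#'   \item holding the phase-1 rates fixed, solve each remaining species' F
#'     to the same criterion.
#' }
#' Each single-species solve is a monotone bisection on depletion; the joint
#' phase alternates per-species bisections to a fixed point.
#'
#' @param om An [om_config()].
#' @param recruit_models Named list of `recruit_model`s (used with zero
#'   process error).
#' @param forcing Persistence `climate_series` covering `years`.
#' @param years Projection years.
#' @param B0 Named unfished reference biomass from [project_unfished()] over
#'   the same `years`/`window`.
#' @param window Year range over which mean SSB is matched to
#'   `target_frac * B0` (default the final five years).
#' @param joint_species Species solved simultaneously in phase 1 (default
#'   the first two).
#' @param target_frac Depletion target (default 0.40).
#' @param tol Relative tolerance on achieved depletion.
#' @param F_max Upper bisection bracket.
#' @param max_outer Maximum joint-phase sweeps.
#' @return Named vector `F_target`, with attribute `"achieved_depletion"`:
#'   each species' end-window mean depletion evaluated under the conditions
#'   of its own solve phase (the quantity the bisection drives to
#'   `target_frac`). With inter-species predation, a species solved in an
#'   earlier phase can drift from the target once later phases adjust other
#'   rates; the attribute records what the procedure itself achieved.
#' @export
solve_F_target <- function(om, recruit_models, forcing, years, B0,
                           window = NULL,
                           joint_species = names(om$species)[1:2],
                           target_frac = 0.40, tol = 1e-6, F_max = 3,
                           max_outer = 60L) {
  stopifnot(inherits(om, "om_config"), inherits(forcing, "climate_series"))
  if (!is_constant_series(forcing)) {
    stop("solve_F_target: reference points are defined only under constant ",
         "(persistence) forcing")
  }
  years <- as.integer(years)
  if (is.null(window)) window <- c(years[length(years)] - 4L,
                                   years[length(years)])
  spp <- names(om$species)
  stopifnot(all(joint_species %in% spp))
  rest <- setdiff(spp, joint_species)
  F_cur <- stats::setNames(rep(0, length(spp)), spp)
  for (sp in rest) F_cur[[sp]] <- om$species[[sp]]$hist_F

  dep_sp <- function(F_vec, sp) {
    .depletion_at_F(om, recruit_models, forcing, years, window, B0,
                    F_vec)[[sp]]
  }
  bisect_sp <- function(F_vec, sp) {
    # depletion is monotone decreasing in own F
    d0 <- dep_sp(`[[<-`(F_vec, sp, 0), sp)
    if (d0 < target_frac - tol) {
      stop(sprintf(
        "solve_F_target: %.0f%% depletion unattainable for '%s' even at F = 0 (got %.4f)",
        100 * target_frac, sp, d0))
    }
    lo <- 0; hi <- F_max
    d_hi <- dep_sp(`[[<-`(F_vec, sp, hi), sp)
    if (d_hi > target_frac) {
      warning(sprintf(
        "solve_F_target: depletion %.4f still above target at F_max for '%s'",
        d_hi, sp))
      return(hi)
    }
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      d <- dep_sp(`[[<-`(F_vec, sp, mid), sp)
      if (abs(d - target_frac) <= tol * target_frac) return(mid)
      if (d > target_frac) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    (lo + hi) / 2
  }

  achieved <- stats::setNames(rep(NA_real_, length(spp)), spp)
  # phase 1: alternate the joint species to a fixed point
  for (outer in seq_len(max_outer)) {
    F_prev <- F_cur
    for (sp in joint_species) {
      F_cur[[sp]] <- bisect_sp(F_cur, sp)
    }
    dep <- .depletion_at_F(om, recruit_models, forcing, years, window, B0,
                           F_cur)
    if (all(abs(dep[joint_species] - target_frac) <= tol * target_frac)) {
      achieved[joint_species] <- dep[joint_species]
      break
    }
    if (outer == max_outer) {
      stop(sprintf(
        "solve_F_target: joint phase did not converge after %d sweeps (last F: %s)",
        max_outer, paste(sprintf("%s=%.5f", joint_species,
                                 F_cur[joint_species]), collapse = ", ")))
    }
    if (max(abs(F_cur - F_prev)) < 1e-12) break
  }
  # phase 2: remaining species, joint rates held fixed
  for (sp in rest) {
    F_cur[[sp]] <- bisect_sp(F_cur, sp)
    achieved[[sp]] <- .depletion_at_F(om, recruit_models, forcing, years,
                                      window, B0, F_cur)[[sp]]
  }
  attr(F_cur, "achieved_depletion") <- achieved
  F_cur
}
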