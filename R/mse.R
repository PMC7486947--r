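#' Run one closed-loop scenario projection
#'
#' The three-step annual loop over the projection years, for one climate
#' scenario, one management variant and one recruitment parameter replicate:
#' \enumerate{
#'   \item project the population into year `y` (climate-driven recruitment,
#'     weight and predation) and compute each species' ABC by applying the
#'     sloping control rule to start-of-year spawning biomass against the
#'     climate-naive reference points;
#'   \item map ABC to TAC — identity for the `hcr_no_cap` variant, the
#'     catch-function ensemble followed by the proportional 2 MT cap for
#'     `hcr_with_cap`;
#'   \item map TAC to realized catch (`catch = ABC` without the cap; the
#'     TAC-to-catch regression with it), convert catch to an effective
#'     fishing mortality and remove it while advancing the year.
#' }
#' `no_fishing` applies `F = 0` throughout.
#'
#' @param om An [om_config()].
#' @param recruit_models Named list of `recruit_model`s (one parameter
#'   replicate per species).
#' @param forcing `climate_series` covering `years`.
#' @param policy A [harvest_policy()] with climate-naive reference points.
#' @param variant One of `"no_fishing"`, `"hcr_no_cap"`, `"hcr_with_cap"`.
#' @param years Projection years.
#' @param catch_model A [fit_catch_functions()] model (required for
#'   `hcr_with_cap`).
#' @param eps_mat Optional years x species matrix of log-scale recruitment
#'   deviates (rownames = years); zero deviates when NULL.
#' @param exogenous_other_tac Fixed TAC block (tons) for stocks outside the
#'   model, counted against the cap (default 0: the cap applies dynamically
#'   to the focal species only).
#' @param indicators_vals Named indicator values passed to the catch
#'   functions (default all zero).
#' @param scenario_id,replicate_id Labels recorded in the output.
#' @return Data frame (one row per species-year): `scenario`, `variant`,
#'   `replicate`, `year`, `species`, `recruits`, `ssb`, `abc`, `tac`,
#'   `catch`, `F`, `bottom_temp`.
#' @export
run_scenario <- function(om, recruit_models, forcing, policy,
                         variant = c("no_fishing", "hcr_no_cap",
                                     "hcr_with_cap"),
                         years, catch_model = NULL, eps_mat = NULL,
                         exogenous_other_tac = 0, indicators_vals = NULL,
                         scenario_id = forcing$scenario_id,
                         replicate_id = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(om, "om_config"), inherits(policy, "harvest_policy"))
  if (variant == "hcr_with_cap" && is.null(catch_model)) {
    stop("run_scenario: variant 'hcr_with_cap' requires a catch_model")
  }
  spp <- names(om$species)
  zero <- stats::setNames(rep(0, length(spp)), spp)

  controller <- function(state) {
    if (variant == "no_fishing") {
      return(list(F = zero, abc = zero, tac = zero))
    }
    F_abc <- vapply(spp, function(sp) sloping_hcr(policy, state$ssb[[sp]], sp),
                    numeric(1))
    abc <- compute_abc(state, om, F_abc)
    if (variant == "hcr_no_cap") {
      # catch equals the harvest limit; effective F is the control-rule F
      return(list(F = F_abc, abc = abc, tac = abc))
    }
    open <- abc > 0
    tac <- zero
    if (any(open)) {
      if (all(open)) {
        tac <- suppressWarnings(predict_tac(catch_model, abc,
                                            indicators_vals))
      } else {
        # closed fisheries contribute no ABC signal; predict with a floor
        # driver and zero them afterwards
        abc_in <- abc; abc_in[!open] <- 1e-6
        tac <- suppressWarnings(predict_tac(catch_model, abc_in,
                                            indicators_vals))
        tac[!open] <- 0
      }
      tac <- apply_cap(tac, exogenous_other_tac, policy$cap)
    }
    catch <- zero
    pos <- tac > 0
    if (any(pos)) {
      tac_in <- tac; tac_in[!pos] <- 1e-6
      catch <- suppressWarnings(predict_catch(catch_model, tac_in,
                                              indicators_vals))
      catch[!pos] <- 0
    }
    F_real <- vapply(spp, function(sp) {
      s <- om$species[[sp]]
      solve_F_from_catch(state$N[[sp]], state$W[[sp]], s$selectivity,
                         state$M[[sp]], catch[[sp]])
    }, numeric(1))
    list(F = F_real, abc = abc, tac = tac)
  }

  res <- .run_projection(om, recruit_models, forcing, years, controller,
                         eps_mat)
  tab <- res$table
  if (any(!is.finite(tab$ssb)) || any(!is.finite(tab$catch))) {
    stop("run_scenario: non-finite state values in output")
  }
  data.frame(scenario = scenario_id, variant = variant,
             replicate = replicate_id, tab, row.names = NULL)
}

#' Run the full scenario x variant x replicate ensemble
#'
#' Draws recruitment-parameter replicates once (joint multivariate-normal
#' draws shared across scenarios and variants — common random numbers, so a
#' climate-minus-persistence contrast isolates the climate signal) and one
#' process-error deviate array per replicate-year (shared across variants and
#' scenarios within a replicate), then runs every combination. The
#' persistence scenario must be part of `forcing_list`: it is the baseline of
#' all relative-change metrics.
#'
#' @param forcing_list Named list of `climate_series`, including one named
#'   `"persistence"`.
#' @param om An [om_config()].
#' @param recruit_fit Named list of fitted `recruit_model`s (with sampling
#'   covariance).
#' @param policy A [harvest_policy()].
#' @param catch_model A [fit_catch_functions()] model (needed if
#'   `"hcr_with_cap"` is among the variants).
#' @param years Projection years.
#' @param variants Management variants to run.
#' @param n_reps Named replicate counts per variant. The study convention is
#'   100 for `no_fishing` and `hcr_no_cap` and 30 for `hcr_with_cap`.
#' @param base_seed Integer seed controlling both parameter draws and
#'   process-error deviates; reruns are bit-identical.
#' @param exogenous_other_tac,indicators_vals Passed to [run_scenario()].
#' @param out_dir Optional directory: each scenario x variant x replicate
#'   table is also streamed to a CSV as it completes.
#' @return Long data frame concatenating every [run_scenario()] result.
#' @export
run_ensemble <- function(forcing_list, om, recruit_fit, policy,
                         catch_model = NULL, years,
                         variants = c("no_fishing", "hcr_no_cap",
                                      "hcr_with_cap"),
                         n_reps = c(no_fishing = 100L, hcr_no_cap = 100L,
                                    hcr_with_cap = 30L),
                         base_seed = 1L, exogenous_other_tac = 0,
                         indicators_vals = NULL, out_dir = NULL) {
  if (!"persistence" %in% names(forcing_list)) {
    stop("run_ensemble: forcing_list must include a 'persistence' scenario")
  }
  stopifnot(all(variants %in% names(n_reps)), all(n_reps[variants] >= 1L))
  spp <- names(om$species)
  years <- as.integer(years)
  n_max <- max(n_reps[variants])

  # parameter replicates: one joint draw set per species, reused across
  # variants/scenarios (replicate r always gets draw r)
  draws <- lapply(seq_along(spp), function(i) {
    draw_parameter_replicates(recruit_fit[[spp[i]]], n_max,
                              seed = base_seed + i)
  })
  names(draws) <- spp

  # process-error deviates: replicate x year x species, scaled by each
  # species' fitted sigma
  set.seed(base_seed)
  eps_raw <- array(stats::rnorm(n_max * length(years) * length(spp)),
                   dim = c(n_max, length(years), length(spp)),
                   dimnames = list(NULL, years, spp))
  sig <- vapply(spp, function(sp) recruit_fit[[sp]]$sigma, numeric(1))

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out <- list()
  for (variant in variants) {
    for (sc in names(forcing_list)) {
      for (r in seq_len(n_reps[[variant]])) {
        eps_mat <- sweep(eps_raw[r, , , drop = TRUE], 2L, sig, `*`)
        if (length(years) == 1L) eps_mat <- matrix(eps_mat, 1L,
                                                   dimnames = list(years, spp))
        rm_r <- lapply(spp, function(sp) draws[[sp]][[r]])
        names(rm_r) <- spp
        res <- run_scenario(om, rm_r, forcing_list[[sc]], policy, variant,
                            years, catch_model = catch_model,
                            eps_mat = eps_mat,
                            exogenous_other_tac = exogenous_other_tac,
                            indicators_vals = indicators_vals,
                            scenario_id = sc, replicate_id = r)
        if (!is.null(out_dir)) {
          utils::write.csv(res, file.path(out_dir,
            sprintf("run_%s_%s_r%03d.csv", sc, variant, r)),
            row.names = FALSE)
        }
        out[[sprintf("%s_%s_%d", sc, variant, r)]] <- res
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
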