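#' Annual climate-index series for one scenario
#'
#' Container for the environmental covariates that drive recruitment, growth
#' and predation: survey-replicated mean summer bottom temperature (degrees C),
#' residual cold-pool extent (fraction of the shelf, 0-1), and spring and fall
#' large-zooplankton indices (relative abundance units). One value per
#' contiguous calendar year.
#'
#' @param scenario_id Character label ("hindcast", "persistence",
#'   "rcp45_gcm1", ...).
#' @param years Integer vector of calendar years, strictly increasing by 1.
#' @param indices Named list of numeric vectors, one per covariate, each the
#'   same length as `years`. The conventional names are `bottom_temp`,
#'   `cold_pool`, `zoop_spring`, `zoop_fall`, but any named set is accepted.
#' @return An object of class `climate_series`.
#' @seealso [bias_correct()], [make_persistence()], [generate_forcing()]
#' @export
climate_series <- function(scenario_id, years, indices) {
  stopifnot(is.character(scenario_id), length(scenario_id) == 1L)
  years <- as.integer(years)
  if (length(years) == 0L) stop("climate_series: empty year range")
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("climate_series: years must be contiguous and strictly increasing")
  }
  if (!is.list(indices) || is.null(names(indices)) || any(names(indices) == "")) {
    stop("climate_series: indices must be a fully named list")
  }
  for (nm in names(indices)) {
    v <- as.numeric(indices[[nm]])
    if (length(v) != length(years)) {
      stop(sprintf("climate_series: index '%s' has length %d, expected %d",
                   nm, length(v), length(years)))
    }
    indices[[nm]] <- v
  }
  if ("cold_pool" %in% names(indices)) {
    cp <- indices$cold_pool
    if (any(cp < -1e-12 | cp > 1 + 1e-12)) {
      stop("climate_series: cold_pool values must lie in [0, 1]")
    }
    indices$cold_pool <- pmin(pmax(cp, 0), 1)
  }
  structure(list(scenario_id = scenario_id, years = years, indices = indices),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> scenario '%s': %d years (%d-%d), indices: %s\n",
              x$scenario_id, length(x$years), min(x$years), max(x$years),
              paste(names(x$indices), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.climate_series <- function(x, ...) {
  do.call(rbind, lapply(names(x$indices), function(nm) {
    data.frame(scenario = x$scenario_id, year = x$years, index_name = nm,
               value = x$indices[[nm]])
  }))
}

#' Reference-period configuration for delta-method bias correction
#'
#' @param ref_start,ref_end Inclusive calendar-year bounds of the hindcast
#'   reference period (default 2006-2017).
#' @param min_sd Guard on the projection's reference-period standard
#'   deviation; below this the variance-ratio rescaling is ill-posed.
#' @return An object of class `bias_correction_config`.
#' @export
bias_correction_config <- function(ref_start = 2006L, ref_end = 2017L,
                                   min_sd = 1e-8) {
  stopifnot(ref_end >= ref_start, min_sd > 0)
  structure(list(ref_years = seq.int(as.integer(ref_start),
                                     as.integer(ref_end)),
                 min_sd = min_sd),
            class = "bias_correction_config")
}

.series_slice <- function(x, years) {
  idx <- match(years, x$years)
  if (anyNA(idx)) {
    stop(sprintf("scenario '%s' is missing required years: %s", x$scenario_id,
                 paste(years[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Delta-method bias correction of a projected index series
#'
#' Rescales each projected index so that over the reference years its mean and
#' standard deviation equal those of the hindcast:
#' `T'_y = mean(hind, ref) + sd(hind, ref) / sd(fut, ref) * (T_y - mean(fut, ref))`.
#' The unequal-variance form: anomalies from the projection's own reference
#' mean are scaled by the hindcast/projection SD ratio (sample SD, n-1
#' denominator) before re-centring on the hindcast reference mean.
#'
#' Each index is corrected independently. A corrected `cold_pool` index is
#' clipped back into [0, 1]; clips are reported with a warning.
#'
#' @param fut `climate_series` to correct (must span the reference years).
#' @param hind Hindcast `climate_series` (must span the reference years).
#' @param cfg A [bias_correction_config()].
#' @return A `climate_series` with the same years as `fut`.
#' @export
bias_correct <- function(fut, hind, cfg = bias_correction_config()) {
  stopifnot(inherits(fut, "climate_series"), inherits(hind, "climate_series"),
            inherits(cfg, "bias_correction_config"))
  common <- intersect(names(fut$indices), names(hind$indices))
  if (length(common) == 0L) stop("bias_correct: no shared indices")
  i_fut <- .series_slice(fut, cfg$ref_years)
  i_hind <- .series_slice(hind, cfg$ref_years)
  out <- fut$indices
  for (nm in common) {
    fr <- fut$indices[[nm]][i_fut]
    hr <- hind$indices[[nm]][i_hind]
    s_fut <- stats::sd(fr)
    if (!is.finite(s_fut) || s_fut <= cfg$min_sd) {
      stop(sprintf(
        "bias_correct: degenerate reference-period variance for index '%s' (sd = %g)",
        nm, s_fut))
    }
    corrected <- mean(hr) + stats::sd(hr) / s_fut * (fut$indices[[nm]] - mean(fr))
    if (nm == "cold_pool") {
      n_clip <- sum(corrected < 0 | corrected > 1)
      if (n_clip > 0L) {
        warning(sprintf(
          "bias_correct: clipped %d cold_pool value(s) to [0, 1] in scenario '%s'",
          n_clip, fut$scenario_id))
        corrected <- pmin(pmax(corrected, 0), 1)
      }
    }
    out[[nm]] <- corrected
  }
  climate_series(fut$scenario_id, fut$years, out)
}

#' Persistence scenario: indices frozen at the hindcast reference mean
#'
#' Builds the counterfactual forcing in which every index is held constant at
#' its hindcast mean over the reference years (default 2006-2017). This
#' scenario is the baseline against which climate-scenario declines are
#' measured and the forcing under which climate-naive reference points are
#' defined.
#'
#' @param hind Hindcast `climate_series`.
#' @param cfg A [bias_correction_config()].
#' @param projection_years Integer years the persistence series should span.
#' @return A constant `climate_series` with `scenario_id = "persistence"`.
#' @export
make_persistence <- function(hind, cfg = bias_correction_config(),
                             projection_years) {
  stopifnot(inherits(hind, "climate_series"))
  projection_years <- as.integer(projection_years)
  if (length(projection_years) == 0L) {
    stop("make_persistence: empty projection year range")
  }
  i_ref <- .series_slice(hind, cfg$ref_years)
  idx <- lapply(hind$indices, function(v) {
    rep(mean(v[i_ref]), length(projection_years))
  })
  climate_series("persistence", projection_years, idx)
}

#' Is a series constant in every index?
#'
#' Reference points are climate-naive by construction: the solvers refuse any
#' forcing whose indices vary through time. Used as that interface guard.
#'
#' @param x A `climate_series`.
#' @param tol Absolute tolerance on within-index variation.
#' @return Logical scalar.
#' @export
is_constant_series <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "climate_series"))
  all(vapply(x$indices, function(v) diff(range(v)) <= tol, logical(1)))
}

#' Configuration for the synthetic climate-forcing generator
#'
#' Stands in for an ensemble of downscaled GCM projections: each projection
#' scenario is a linear warming trend with interannual Gaussian noise and an
#' additive model bias (removed later by [bias_correct()]). Zooplankton
#' indices respond linearly (negatively, by default) to the temperature
#' anomaly; cold-pool extent shrinks with temperature through a logistic link
#' so it stays in [0, 1].
#'
#' @param hindcast_years,projection_years Integer year vectors. Projections
#'   must overlap the hindcast on the bias-correction reference period.
#' @param base_temp Hindcast mean summer bottom temperature (deg C).
#' @param noise_sd Interannual SD of the temperature noise (deg C, >= 0).
#' @param scenarios Data frame with columns `scenario` (label), `rate`
#'   (deg C per year), `bias` (additive model bias, deg C) and optionally
#'   `freeze_after` (year after which conditions are held at that year's
#'   trend level; NA = never). Defaults emulate two emission tiers (moderate
#'   ~0.022 deg C/yr, high ~0.042 deg C/yr) times three GCM-like variants.
#' @param zoop_slope Change in zooplankton index per deg C of temperature
#'   anomaly (negative: warming depletes large zooplankton).
#' @param zoop_base Named baseline levels for `zoop_spring` / `zoop_fall`.
#' @param zoop_noise_sd Interannual SD of zooplankton noise.
#' @param cold_pool_pars `c(intercept, slope, noise_sd)` of the logistic
#'   cold-pool response to temperature:
#'   `plogis(intercept - slope * temp + noise)`. The logit-scale noise keeps
#'   the index in [0, 1] while decoupling it from temperature year-to-year
#'   (ice dynamics are not a deterministic function of mean bottom
#'   temperature).
#' @param seed Integer RNG seed; fixed seed implies bit-identical output.
#' @return An object of class `forcing_config`.
#' @export
forcing_config <- function(hindcast_years = 1979:2017,
                           projection_years = 2006:2100,
                           base_temp = 1.5,
                           noise_sd = 0.35,
                           scenarios = NULL,
                           zoop_slope = -0.8,
                           zoop_base = c(zoop_spring = 4, zoop_fall = 3),
                           zoop_noise_sd = 0.25,
                           cold_pool_pars = c(1.0, 1.2, 0.4),
                           seed = 1L) {
  if (length(hindcast_years) <= 0L || length(projection_years) <= 0L) {
    stop("forcing_config: year counts must be positive")
  }
  if (noise_sd < 0 || zoop_noise_sd < 0) {
    stop("forcing_config: noise SDs must be non-negative")
  }
  if (is.null(scenarios)) {
    scenarios <- data.frame(
      scenario = c("rcp45_gcm1", "rcp45_gcm2", "rcp45_gcm3",
                   "rcp85_gcm1", "rcp85_gcm2", "rcp85_gcm3"),
      rate = c(0.022 * c(0.8, 1.0, 1.2), 0.042 * c(0.8, 1.0, 1.2)),
      bias = c(0.4, -0.3, 0.2, 0.4, -0.3, 0.2),
      freeze_after = NA_integer_
    )
  }
  stopifnot(all(c("scenario", "rate", "bias") %in% names(scenarios)))
  if (is.null(scenarios$freeze_after)) scenarios$freeze_after <- NA_integer_
  structure(list(hindcast_years = as.integer(hindcast_years),
                 projection_years = as.integer(projection_years),
                 base_temp = base_temp, noise_sd = noise_sd,
                 scenarios = scenarios, zoop_slope = zoop_slope,
                 zoop_base = zoop_base, zoop_noise_sd = zoop_noise_sd,
                 cold_pool_pars = cold_pool_pars, seed = as.integer(seed)),
            class = "forcing_config")
}

.make_indices <- function(cfg, temp) {
  n <- length(temp)
  anom <- temp - cfg$base_temp
  zn <- if (cfg$zoop_noise_sd > 0) {
    matrix(stats::rnorm(2L * n, 0, cfg$zoop_noise_sd), n, 2L)
  } else matrix(0, n, 2L)
  cp_sd <- if (length(cfg$cold_pool_pars) >= 3L) cfg$cold_pool_pars[3] else 0
  cpn <- if (cp_sd > 0) stats::rnorm(n, 0, cp_sd) else 0
  list(
    bottom_temp = temp,
    cold_pool = stats::plogis(cfg$cold_pool_pars[1] - cfg$cold_pool_pars[2] * temp + cpn),
    zoop_spring = cfg$zoop_base[["zoop_spring"]] + cfg$zoop_slope * anom + zn[, 1L],
    zoop_fall = cfg$zoop_base[["zoop_fall"]] + cfg$zoop_slope * anom + zn[, 2L]
  )
}

#' Generate a synthetic hindcast plus an ensemble of warming projections
#'
#' Emulates downscaled multi-GCM forcing: one hindcast series around the
#' baseline temperature, plus one raw (uncorrected) projection per configured
#' scenario, each a linear trend anchored at the projection start with its own
#' additive bias and shared interannual noise SD. Projections overlap the
#' hindcast over the bias-correction reference period, so they can be
#' delta-corrected before use.
#'
#' @param cfg A [forcing_config()].
#' @return Named list of `climate_series`: `hindcast` first, then one element
#'   per projection scenario.
#' @export
generate_forcing <- function(cfg = forcing_config()) {
  stopifnot(inherits(cfg, "forcing_config"))
  set.seed(cfg$seed)
  out <- list()

  hy <- cfg$hindcast_years
  t_hind <- cfg$base_temp +
    (if (cfg$noise_sd > 0) stats::rnorm(length(hy), 0, cfg$noise_sd)
     else rep(0, length(hy)))
  out$hindcast <- climate_series("hindcast", hy, .make_indices(cfg, t_hind))

  py <- cfg$projection_years
  for (i in seq_len(nrow(cfg$scenarios))) {
    sc <- cfg$scenarios[i, ]
    elapsed <- py - py[1L]
    if (!is.na(sc$freeze_after)) {
      elapsed <- pmin(elapsed, sc$freeze_after - py[1L])
    }
    trend <- cfg$base_temp + sc$bias + sc$rate * elapsed
    temp <- trend +
      (if (cfg$noise_sd > 0) stats::rnorm(length(py), 0, cfg$noise_sd)
       else rep(0, length(py)))
    out[[sc$scenario]] <- climate_series(sc$scenario, py,
                                         .make_indices(cfg, temp))
  }
  out
}

#' Write / read climate series as long-format CSV
#'
#' Columns: scenario, year, index_name, value.
#'
#' @param series A `climate_series` or list of them.
#' @param file Path to a CSV file.
#' @return `write_forcing_csv` returns `file` invisibly; `read_forcing_csv`
#'   returns a named list of `climate_series`.
#' @export
write_forcing_csv <- function(series, file) {
  if (inherits(series, "climate_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(file) {
  df <- utils::read.csv(file)
  stopifnot(all(c("scenario", "year", "index_name", "value") %in% names(df)))
  out <- lapply(split(df, df$scenario), function(d) {
    years <- sort(unique(d$year))
    idx <- lapply(split(d, d$index_name), function(dd) {
      dd$value[order(dd$year)]
    })
    climate_series(d$scenario[1L], years, idx)
  })
  out[unique(df$scenario)]
}
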