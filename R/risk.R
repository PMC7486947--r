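#' Relative change of a series against its paired persistence baseline
#'
#' `delta_y = (x_y - p_y) / p_y` elementwise. Years where the persistence
#' value is zero are masked to `NA` with a warning (a zero baseline leaves
#' the relative change undefined); a zero scenario value over a positive
#' baseline gives exactly -1.
#'
#' @param x Numeric series under a climate scenario.
#' @param p Paired persistence series (same length, same years).
#' @param years Optional year labels of `x`.
#' @param years_p Optional year labels of `p`; must match `years` exactly.
#' @return Numeric vector of relative changes.
#' @export
delta_vs_persistence <- function(x, p, years = NULL, years_p = years) {
  if (length(x) != length(p)) {
    stop("delta_vs_persistence: series lengths differ")
  }
  if (!is.null(years) && !identical(as.integer(years), as.integer(years_p))) {
    stop("delta_vs_persistence: series are not year-aligned")
  }
  out <- (x - p) / p
  zero <- p == 0
  if (any(zero)) {
    warning(sprintf(
      "delta_vs_persistence: %d year(s) with zero baseline masked to NA",
      sum(zero)))
    out[zero] <- NA_real_
  }
  out
}

#' Probabilities of decline, severe decline and collapse by period
#'
#' For each species x variant x scenario x period cell, computes the fraction
#' of replicates whose period-mean relative change versus the paired
#' persistence run (same variant, same replicate) falls below minus the
#' threshold (strict inequality). Default thresholds: decline > 10%, severe
#' decline > 50%, collapse > 80%. Nested thresholds are monotone by
#' construction: P(collapse) <= P(severe) <= P(decline).
#'
#' @param results Ensemble output of [run_ensemble()] (must include the
#'   persistence scenario for every variant/replicate present).
#' @param metric Column to evaluate: `"catch"` or `"ssb"`.
#' @param thresholds Named decline thresholds (proportions).
#' @param periods List of length-2 year ranges; defaults to four equal
#'   windows over the projection span.
#' @param period_stat `"mean"` (period-mean relative change, default) or
#'   `"any"` (worst year within the period).
#' @return Long data frame: `species`, `variant`, `scenario`, `period`,
#'   `threshold`, `probability`, `n_replicates`.
#' @export
risk_probability <- function(results, metric = c("catch", "ssb"),
                             thresholds = c(decline = 0.10, severe = 0.50,
                                            collapse = 0.80),
                             periods = NULL,
                             period_stat = c("mean", "any")) {
  metric <- match.arg(metric)
  period_stat <- match.arg(period_stat)
  stopifnot(is.data.frame(results),
            all(c("scenario", "variant", "replicate", "year", "species",
                  metric) %in% names(results)))
  if (!"persistence" %in% results$scenario) {
    stop("risk_probability: ensemble lacks the persistence baseline")
  }
  yrs <- range(results$year)
  if (is.null(periods)) {
    edges <- round(seq(yrs[1L], yrs[2L] + 1L, length.out = 5L))
    periods <- lapply(1:4, function(i) c(edges[i], edges[i + 1L] - 1L))
  }
  for (p in periods) {
    if (!any(results$year >= p[1L] & results$year <= p[2L])) {
      stop(sprintf("risk_probability: empty period %d-%d", p[1L], p[2L]))
    }
  }
  pers <- results[results$scenario == "persistence", ]
  clim <- results[results$scenario != "persistence", ]
  if (nrow(clim) == 0L) stop("risk_probability: no climate scenarios present")

  key <- function(d) paste(d$variant, d$replicate, d$species, d$year, sep = "|")
  pers_val <- stats::setNames(pers[[metric]], key(pers))
  clim$baseline <- pers_val[key(clim)]
  if (anyNA(clim$baseline)) {
    stop("risk_probability: unpaired replicate/year against persistence")
  }
  suppressWarnings(
    clim$delta <- delta_vs_persistence(clim[[metric]], clim$baseline))

  cells <- expand.grid(period = seq_along(periods),
                       threshold = names(thresholds),
                       stringsAsFactors = FALSE)
  combos <- unique(clim[, c("species", "variant", "scenario")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    d <- clim[clim$species == combos$species[i] &
                clim$variant == combos$variant[i] &
                clim$scenario == combos$scenario[i], ]
    for (j in seq_len(nrow(cells))) {
      p <- periods[[cells$period[j]]]
      dp <- d[d$year >= p[1L] & d$year <= p[2L], ]
      stat <- tapply(dp$delta, dp$replicate, function(v) {
        if (period_stat == "mean") mean(v, na.rm = TRUE) else
          min(v, na.rm = TRUE)
      })
      thr <- thresholds[[cells$threshold[j]]]
      out[[length(out) + 1L]] <- data.frame(
        species = combos$species[i], variant = combos$variant[i],
        scenario = combos$scenario[i],
        period = sprintf("%d-%d", p[1L], p[2L]),
        threshold = cells$threshold[j],
        probability = mean(stat < -thr, na.rm = TRUE),
        n_replicates = length(stat))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect multiyear warm stanzas in a temperature series
#'
#' Maximal runs of consecutive years with temperature strictly above the
#' threshold, reported only when at least `run_length` years long. The study
#' convention is 2.1 deg C and five consecutive years.
#'
#' @param years Integer years (contiguous).
#' @param temp Temperature series (same length).
#' @param threshold Temperature threshold (deg C, default 2.1).
#' @param run_length Minimum run length in years (default 5).
#' @return Data frame with columns `start_year`, `end_year`, `length`
#'   (zero rows when no stanza qualifies), sorted and non-overlapping.
#' @export
detect_warm_stanzas <- function(years, temp, threshold = 2.1,
                                run_length = 5L) {
  stopifnot(length(years) == length(temp), length(years) > 0L)
  above <- temp > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= run_length
  out <- data.frame(start_year = as.integer(years[starts[hit]]),
                    end_year = as.integer(years[ends[hit]]),
                    length = r$lengths[hit])
  out[order(out$start_year), , drop = FALSE]
}
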