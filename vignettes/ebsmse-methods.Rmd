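---
title: "Climate-enhanced multispecies MSE: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-enhanced multispecies MSE: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebsmse)
```

`ebsmse` is a closed-loop management strategy evaluation (MSE) for a
three-species eastern Bering Sea groundfish complex — a pollock-like gadid, a
Pacific-cod-like gadid and an arrowtooth-flounder-like flatfish — under
climate forcing. The closed loop couples five layers: climate forcing,
climate-enhanced recruitment, an age-structured multispecies operating model,
harvest policy (control rule plus an ecosystem-level catch cap implemented
through empirical catch functions), and evaluation (risk metrics and thermal
tipping-point detection). This vignette documents the model in each layer,
the defaults and why they were chosen, and where design was genuinely open,
the choice made.

## Climate forcing and bias correction

A scenario is an annual series of four covariates: survey-mean summer bottom
temperature (°C), residual cold-pool extent (fraction of the shelf in 0–1),
and spring and fall large-zooplankton indices (relative units). The synthetic
generator emulates an ensemble of downscaled projections: each scenario is a
linear warming trend (°C yr⁻¹) with Gaussian interannual noise (default SD
0.35 °C) and an additive model bias; six default scenarios pair two
emission-like tiers (≈0.022 and ≈0.042 °C yr⁻¹, bracketing ~1–2.5 °C and
~2–4.5 °C of warming over roughly 80 years) with three GCM-like rate
variants. Zooplankton responds linearly and negatively (default −0.8 index
units per °C of anomaly: warming depletes large, lipid-rich zooplankton);
cold-pool extent shrinks through a logistic link in temperature with its own
logit-scale noise (SD 0.4), which keeps the index in [0, 1] while avoiding a
deterministic — and statistically degenerate — mapping from temperature.

Projections are corrected to the hindcast with the unequal-variance delta
method: over the reference years (2006–2017) the corrected series is forced
to match the hindcast mean and standard deviation exactly, by scaling
anomalies with the hindcast/projection SD ratio (sample SD, n−1). Each index
is corrected independently, on its raw scale; corrected cold-pool values are
clipped back to [0, 1] with a warning. The correction is undefined for a
series with (near-)zero reference-period variance — the variance ratio is
0/0 — so the implementation refuses it rather than returning the input; the
persistence scenario is therefore built directly, never passed through the
correction. The *persistence* scenario holds every index constant at its
2006–2017 hindcast mean; it is both the baseline of all relative-change
metrics and the only forcing under which reference points may be computed.

A `freeze_after` flag on any scenario holds its trend at a given year's
level thereafter, generalizing the common situation in which one ensemble
member's late-century output is unavailable and conditions are carried
forward.

## Climate-enhanced recruitment

Recruitment follows a Ricker-type recruits-per-spawner model with covariates
on the log scale:

ln R(y) = α − β₀ B(y−1) + ln B(y−1) + Σⱼ βⱼ X(j, y) + ε(y),  ε ~ N(0, σ²).

Fitting is ordinary least squares of ln(R/B) on (B, X) — the Gaussian
maximum-likelihood estimate for this model — with the residual SD taken from
the df-corrected estimator and the full coefficient sampling covariance
retained. Parameter-uncertainty replicates are joint multivariate-normal
draws from that covariance (whether the original study drew jointly or
marginally is not documented; joint draws are the default and a `marginal`
option exists). Process error in projections is drawn i.i.d. N(0, σ²) per
species-year on the log scale, with no autocorrelation. The default
covariate set is the four indices above, configurable per species.

## Operating model

Each species is an age-structured stock (10–12 ages; the oldest age a plus
group) with maturity, average fishery selectivity and residual natural
mortality M1 at age. Units: numbers-at-age in thousands of fish, weight in
kg, so Σ N·W is metric tons. Two climate channels besides recruitment:

* **Growth** — weight-at-age is the baseline schedule times
  g(a) = 1 + s·a, where a is the bottom-temperature anomaly relative to the
  2006–2017 mean and s is a per-species sensitivity (defaults −0.01 to
  −0.02 /°C: warming reduces size-at-age). g is clamped below at 10% of
  baseline with a warning.
* **Predation** — M2 for a prey age is Σ over predators of
  coef × vulnerability(age) × predator biomass × exp(slope × anomaly):
  linear in predator biomass and exponentially increasing with temperature
  (default slope 0.08 /°C). This is a transparent configurable stand-in for
  a bioenergetics predation sub-model, which is out of scope; the defaults
  make cod and arrowtooth (and cannibalism) significant sources of age-1
  pollock mortality.

The annual update applies Z = M1 + M2 + S·F through year y−1, promotes
survivors, and injects recruitment at age 1 computed from spawning biomass
at the start of year y−1 and year-y covariates. Catch is Baranov:
C = Σₐ (Sₐ F / Zₐ)(1 − e^{−Zₐ}) Nₐ Wₐ. The conventions not pinned down by
the source methodology — recruitment age 1, one-year spawner lag,
start-of-year spawning, continuous F within Baranov — are the simplest ones
consistent with the recruitment model's B(y−1), and are asserted by the test
suite's independent plain-loop oracle rather than claimed to match any
specific assessment.

The inverse problem (effective F given a target catch) is solved by
bracketed root finding on [0, F_max = 5 yr⁻¹] to 10⁻⁸ relative tolerance;
targets beyond the attainable catch at F_max are taken at F_max with the
shortfall logged.

## Reference points and harvest policy

Reference points are deliberately *climate-naive*: computed once under
persistence forcing and never updated, mirroring status-quo practice. The
solvers enforce this at the interface — non-constant forcing is refused.

1. B0 is the mean unfished (F = 0) spawning biomass over 2095–2099 under
   persistence.
2. F_target solves, by bisection on the end-window depletion, for 40% of B0:
   first jointly for the two gadids (alternating per-species bisections to a
   fixed point, with the flatfish held at its historical-average F), then
   for the flatfish with the gadid rates fixed.

Because the flatfish preys on juvenile pollock, raising its F in phase 2
releases predation and lifts the gadids' realized depletion above 40%; the
sequential procedure only guarantees the target *under each species' own
solve conditions*. The solver therefore reports, per species, the achieved
depletion at its solve phase (`achieved_depletion` attribute); that is the
procedure's self-consistency quantity, converged to 10⁻⁶ relative.

The annual control rule is a sloping rule with ecosystem cutoff: F = F_target
at or above 40% of B0, F = 0 below 20% of B0 and, by default, a straight
line between those endpoints. The exact analytic shape of the ramp between
the stated endpoints was an open choice; the straight line is the default
and the Tier-3-style form F_target·(B/B40 − a)/(1 − a) with a = 0.5 (which
shares both endpoints) is available via `ramp = "tier3"`. ABC is the Baranov
catch at the control-rule F given current numbers, weights and natural
mortality.

## Catch functions and the 2 MT cap

The quota system is modeled empirically in two log-linear stages fitted to a
1992–2017 history: ln TAC on ln(own ABC), other species' ABC levels and 0/1
policy indicators; ln catch on ln TAC analogously. An ensemble of three
members differs only in the assumed residual structure (independent; two
linked groups; all linked — with only three focal species the default
groupings are illustrative, and configurable). Point estimates are
equation-wise OLS; an optional single feasible-GLS pass uses the estimated
cross-equation residual covariance for the grouped members (with column
scaling, since quota levels ~10⁶ would otherwise make the stacked normal
equations numerically singular; degenerate residual covariances skip the
pass). With ~26 annual observations the FGLS and OLS point estimates are
nearly identical, and projections use only the mean relationship, so OLS is
the default. The lognormal retransformation term (σ²/2) is *not* added to
the mean prediction by default — the mean relationship is used as printed —
and predictions are clipped to the management constraints TAC ≤ ABC and
catch ≤ TAC, with clips flagged.

The ecosystem cap (default 2,000,000 t) is applied by a single proportional
scaling of the modeled TACs so the total (plus any fixed exogenous TAC block
for stocks outside the model, default 0) equals the cap exactly; the rule is
idempotent and preserves relative allocations.

Leave-one-out cross-validation refits the ensemble without each year and
accumulates four error metrics per species (sum of differences, of percent
differences, of squared differences, of squared percent differences) against
the held-out year's catch, alongside the same metrics for the naive rule
catch = ABC.

## The closed loop and ensembles

For each projection year: (1) advance the population and apply the control
rule to start-of-year spawning biomass (ABC from start-of-year state — the
within-year timing was an open choice and this is the documented
convention); (2) ABC→TAC (identity without the cap, catch functions plus cap
with it); (3) TAC→catch, catch→effective F, remove. Variants: `no_fishing`
(F = 0), `hcr_no_cap` (catch = ABC at the control-rule F), `hcr_with_cap`
(the full catch-function pathway). Replicate ensembles pair draws across
variants and scenarios (common random numbers — each replicate uses the same
recruitment-parameter draw and the same process-error deviates everywhere),
so a climate-minus-persistence contrast within a replicate isolates the
climate signal. Study-scale replicate counts are 100 (no fishing, no cap)
and 30 (with cap); these are the `run_ensemble()` defaults, while tests and
the worked analyses run 5–15 replicates over shortened horizons.

## Risk metrics

Relative change is Δ = (value − paired persistence value)/persistence value,
per species-year-replicate. Risk per period is the fraction of replicates
whose *period-mean* Δ lies below −0.10 (decline), −0.50 (severe) or −0.80
(collapse), strict inequalities. Period-mean (rather than any-year) is the
default because multi-decade windows are the reporting unit; an `"any"`
option takes the worst year instead. Default periods are four equal windows
over the projection span; the original reporting boundaries are not
documented, so these are explicit arguments everywhere.

## Tipping-point analysis

Pooled (temperature, Δcatch) points per species × variant are smoothed with
a penalized thin-plate regression spline with basis dimension k = 4 (the
anti-overfitting choice; `mgcv` with GCV smoothing-parameter selection).
First and second derivatives are central finite differences on a 200-point
grid. Pointwise 95% bands for the smooth and both derivatives come from a
residual bootstrap (n = 1000 by convention; ≥100 enforced): resample
residuals, refit, re-evaluate. By default the refit holds the smoothing
parameter at the original fit's value, which makes each bootstrap replicate
an exact linear-operator evaluation — deterministic, fast, and standard for
residual bootstraps of penalized splines; per-replicate re-selection is
available (`refit_sp = TRUE`) and agrees closely. The quantile pair for the
bands is (0.025, 0.975). The second-derivative band is additionally smoothed
with a loess of span 10% before use. A tipping point is a grid location
where s″ changes sign and the smoothed s″ CI excludes zero in a flanking
region (±10% of the grid); among qualifying candidates the winner maximizes
min(|lower|, |upper|) over that region (the CI "most different from zero"),
ties broken by larger |s″|. Requiring the flanking s′ CI to exclude zero as
well is deliberately *not* imposed (the s″ criterion is the rule as stated);
significant-slope regions are reported separately.

With k = 4 the smoother is stiff by design: it cannot track a sharp sigmoid
exactly (recovery tests use an adequate basis for exactness and assert only
coarse tracking at k = 4), but inflection *location* is recovered well —
the calibration suite detects a constructed 2.2 °C inflection within
±0.2 °C in ≥80% of 200 seeded replicates (n = 2000 points, 200 bootstrap
draws).

## What the synthetic generator does and does not emulate

The fixture generates every input the pipeline needs with the statistical
structure the analyses assume: warming trends with divergent tiers and
interannual noise, temperature-anticorrelated zooplankton, a bounded
cold-pool index, recruitment observations drawn exactly from the true
climate-enhanced Ricker model, and a quota history drawn exactly from the
true log-linear catch functions with cross-species-correlated lognormal
errors (management constraints enforced). Effect signs follow the mechanism
narrative — warming and zooplankton loss reduce gadid recruitment, the
flatfish is mildly warm-favored — with magnitudes chosen once so that
unfished biomasses sit at realistic levels (pollock ≈ 10 Mt dominant, cod
≈ 1.2 Mt, arrowtooth ≈ 0.8 Mt) and high-tier warming crosses the 2.1 °C
warm-stanza threshold from the 2030s on.

It does **not** emulate: ocean circulation or plankton dynamics (no spatial
fields, no mechanistic NPZ), spatial survey replication (indices are
generated directly at the annual level), bioenergetics predation,
assessment-model estimation error or observation error, the >20-stock TAC
complex (three focal species plus an optional exogenous constant), or
economics. Passing tests therefore demonstrate the *internal consistency*
of the management-evaluation machinery under known structure, not predictive
skill on the real system.

## Numerical conventions and problem sizes

* Depletion solves: bisection to 10⁻⁶ relative on depletion; joint phase
  alternates to a fixed point (≤60 sweeps).
* F-from-catch: `uniroot` on [0, 5] to ~10⁻⁸ relative on catch.
* Reference window: 2095–2099 under the full 2018–2100 horizon (the
  functions default to the final five projection years for shortened
  horizons, and the window is always an explicit argument).
* Test-suite problem sizes: 30–80-year horizons, 5-replicate ensembles,
  200-replicate calibration loops, 120–300 bootstrap draws; the analysis
  drivers run the full horizon with 10–15 replicates and 1000 bootstrap
  draws. These sizes make the whole suite run in about a minute while
  keeping every Monte-Carlo acceptance margin wide.

## Known limitations

Single-region, single-fleet, no implementation error beyond the catch
functions themselves; recruitment deviates are uncorrelated in time, so
regime-like persistence in recruitment is absent; the predation stand-in has
no functional response (predation mortality is linear in predator biomass);
reference points are never re-estimated within the loop (by design, matching
the climate-naive status quo); and the catch-function groupings for the
correlated-residual ensemble members are illustrative defaults for three
species rather than estimates of the real fleet structure.
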