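# ebsmse

Closed-loop, climate-enhanced multispecies **management strategy evaluation
(MSE)** for an eastern Bering Sea groundfish complex (a pollock-like gadid, a
Pacific-cod-like gadid, an arrowtooth-flounder-like flatfish). The package is
for fisheries scientists who want to exercise every stage of an
ecosystem-based harvest-policy evaluation under warming — forcing, stock
dynamics, policy, risk, tipping points — at desk scale, with synthetic data
whose generating truth is known.

The closed loop couples five layers:

1. **Forcing** — synthetic multi-GCM-like warming trajectories with
   delta-method bias correction to a 2006–2017 hindcast reference,
   `T'ᵧ = T̄_hind,ref + (σ_hind,ref/σ_fut,ref)(Tᵧ − T̄_fut,ref)`,
   plus the *persistence* counterfactual (indices frozen at the reference
   mean).
2. **Recruitment** — a Ricker-type recruits-per-spawner model with
   environmental covariates,
   `ln R = α − β₀B + ln B + **B**·**X** + ε`, ε ~ N(0, σ²),
   fitted by Gaussian ML with full coefficient covariance for
   parameter-replicate ensembles.
3. **Operating model** — age-structured multispecies dynamics with
   temperature-dependent weight-at-age and predation mortality, Baranov
   catch `C = Σₐ (SₐF/Zₐ)(1 − e^{−Zₐ})NₐWₐ`.
4. **Policy** — climate-naive reference points (B0 from an unfished
   persistence projection, F_target from a two-phase iterative 40%-depletion
   solve), a sloping harvest control rule with a 20%-of-B0 ecosystem cutoff,
   and the 2-million-ton ecosystem cap applied through an ensemble of
   log-linear ABC→TAC and TAC→catch regressions with proportional reduction.
5. **Evaluation** — probabilities of >10/50/80% decline in catch or biomass
   relative to the paired persistence replicate, warm-stanza detection
   (≥5 consecutive years above 2.1 °C), and GAM-based thermal tipping-point
   detection (k = 4 thin-plate smoother, residual-bootstrap 95% bands on
   s″, loess-smoothed, sign-change-plus-significance rule).

See `vignettes/ebsmse-methods.Rmd` for the full model description,
assumptions, and design choices.

## Worked example

Build the synthetic study system, derive climate-naive reference points
under persistence, and query the control rule:

```r
library(ebsmse)

b  <- make_study_fixture(seed = 1)
p  <- b$forcing$persistence
up <- project_unfished(b$om, b$recruit_true, p, 2018:2100,
                       window = c(2095, 2099))
Ft <- solve_F_target(b$om, b$recruit_true, p, 2018:2100, up$B0,
                     window = c(2095, 2099),
                     joint_species = c("pollock", "cod"))
(pol <- harvest_policy(up$B0, Ft, window = c(2095, 2099)))
#> <harvest_policy> cutoff 20% B0, target 40% B0, cap 2e+06 t, ramp 'linear'
#>   pollock: B0 = 10923961 t, F_target = 0.2223
#>   cod: B0 = 1223456 t, F_target = 0.5360
#>   arrowtooth: B0 = 790468 t, F_target = 0.2567

round(attr(Ft, "achieved_depletion"), 6)
#>    pollock        cod arrowtooth
#>        0.4        0.4        0.4

round(c(at_half_B0  = sloping_hcr(pol, 0.50 * pol$B0[["pollock"]], "pollock"),
        at_30pct_B0 = sloping_hcr(pol, 0.30 * pol$B0[["pollock"]], "pollock"),
        at_15pct_B0 = sloping_hcr(pol, 0.15 * pol$B0[["pollock"]], "pollock")), 4)
#>  at_half_B0 at_30pct_B0 at_15pct_B0
#>      0.2223      0.1111      0.0000
```

The solver drives each species' end-window spawning biomass to exactly 40%
of its unfished level (under its own solve conditions); the control rule
returns the full target rate above 40% of B0, half of it at the ramp
midpoint (30% of B0), and closes the fishery below the 20% cutoff.

## The analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
plain-text tables under `results/`:

| script | what it does | writes |
|---|---|---|
| `01_make_fixture.R` | synthetic forcing, recruitment observations, quota history | `results/fixture/` |
| `02_fit_inputs.R` | recruitment fits; catch-function ensemble + LOO-CV | `recruitment_fit.csv`, `loo_cv.csv` |
| `03_reference_points.R` | B0, F_target, achieved depletion | `reference_points.csv` |
| `04_run_mse.R` | closed-loop ensembles, 3 variants × 3 scenarios | `mse_runs.csv` |
| `05_risk.R` | decline/severe/collapse probabilities by period | `risk_ssb.csv`, `risk_catch.csv` |
| `06_tipping.R` | pooled Δcatch–temperature smooths, tipping points | `tipping_points.csv`, `tipping_grids.csv` |

Run them in order from the repository root, e.g.
`Rscript analysis/04_run_mse.R`.

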