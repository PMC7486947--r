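Package: ebsmse
Title: Climate-Enhanced Multispecies Management Strategy Evaluation for
    Bering Sea Groundfish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop management strategy evaluation (MSE) for an eastern
    Bering Sea groundfish complex under climate change. Provides synthetic
    climate forcing with delta-method bias correction, climate-enhanced
    Ricker recruitment with covariate effects, a simplified multispecies
    age-structured operating model with temperature-dependent growth and
    predation and Baranov catch, Tier-3 sloping harvest control rules with an
    ecosystem-level 2 million ton catch cap implemented through log-linear
    ABC-to-TAC and TAC-to-catch regressions, risk-of-decline metrics relative
    to a climate persistence baseline, and GAM-based thermal tipping-point
    detection with residual-bootstrap derivative confidence bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
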