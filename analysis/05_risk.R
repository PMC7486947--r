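#!/usr/bin/env Rscript
# Step 5 - risk of decline, severe decline and collapse.
#
# For each species x variant x scenario and four ~21-year periods over
# 2018-2100, computes the probability that the period-mean decline relative
# to the paired persistence replicate exceeds 10% (decline), 50% (severe)
# and 80% (collapse), for catch (fished variants) and spawning biomass.
# Reads the ensemble written by analysis/04_run_mse.R.

library(ebsmse)

res <- read.csv("results/mse_runs.csv")

risk_ssb <- risk_probability(res, metric = "ssb")
write.csv(risk_ssb, "results/risk_ssb.csv", row.names = FALSE)

fished <- res[res$variant != "no_fishing", ]
risk_catch <- risk_probability(fished, metric = "catch")
write.csv(risk_catch, "results/risk_catch.csv", row.names = FALSE)

cat("Probability of severe decline / collapse in CATCH, final period,",
    "high-emission scenario:\n")
last_p <- sort(unique(risk_catch$period))[length(unique(risk_catch$period))]
show <- risk_catch[risk_catch$period == last_p &
                     risk_catch$scenario == "rcp85" &
                     risk_catch$threshold %in% c("severe", "collapse"), ]
print(show[order(show$species, show$variant, show$threshold),
           c("species", "variant", "threshold", "probability")],
      row.names = FALSE)

cat("\nProbability of a >10% SSB decline by period (pollock, with cap, rcp85):\n")
show2 <- risk_ssb[risk_ssb$species == "pollock" &
                    risk_ssb$variant == "hcr_with_cap" &
                    risk_ssb$scenario == "rcp85" &
                    risk_ssb$threshold == "decline", ]
print(show2[, c("period", "probability")], row.names = FALSE)
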