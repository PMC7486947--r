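# Independent spreadsheet-style oracle for the age-structured projection.
#
# Deliberately written as plain explicit loops over scalar arithmetic, using
# only configuration values from the toy bundle — no package dynamics code.
# Conventions (documented in the package): recruitment enters at age 1 with a
# one-year lag from spawning biomass; oldest age is a plus group; weights
# scale as 1 + sens * anomaly; predation is coef * vuln * predator biomass *
# exp(slope * anomaly); catch is Baranov.

toy_oracle_trajectory <- function(toy, F_applied = toy$F) {
  om <- toy$om
  spp <- names(om$species)
  years <- toy$years
  temps <- toy$forcing$indices$bottom_temp

  weights_at <- function(s, anomaly) {
    w <- numeric(s$n_ages)
    for (a in 1:s$n_ages) {
      g <- 1 + s$thermal_w_sens * anomaly
      if (g < s$w_floor_frac) g <- s$w_floor_frac
      w[a] <- s$w_base[a] * g
    }
    w
  }
  # initial equilibrium age structure from M1 alone
  N <- list()
  for (sp in spp) {
    s <- om$species[[sp]]
    n <- numeric(s$n_ages)
    n[1] <- s$init_recruits
    for (a in 2:s$n_ages) n[a] <- n[a - 1] * exp(-s$M1[a - 1])
    sA <- exp(-s$M1[s$n_ages])
    if (sA < 1) n[s$n_ages] <- n[s$n_ages] / (1 - sA)
    N[[sp]] <- n
  }

  state_quants <- function(N, anomaly) {
    W <- list(); bio <- numeric(0)
    for (sp in spp) {
      W[[sp]] <- weights_at(om$species[[sp]], anomaly)
      b <- 0
      for (a in 1:om$species[[sp]]$n_ages) b <- b + N[[sp]][a] * W[[sp]][a]
      bio[sp] <- b
    }
    M2 <- list()
    for (sp in spp) M2[[sp]] <- numeric(om$species[[sp]]$n_ages)
    for (p in om$predation$pairs) {
      v <- rep_len(p$vuln, om$species[[p$prey]]$n_ages)
      for (a in seq_along(v)) {
        M2[[p$prey]][a] <- M2[[p$prey]][a] +
          p$coef * v[a] * bio[[p$predator]] * exp(p$temp_slope * anomaly)
      }
    }
    ssb <- numeric(0)
    for (sp in spp) {
      s <- om$species[[sp]]
      x <- 0
      for (a in 1:s$n_ages) x <- x + s$maturity[a] * N[[sp]][a] * W[[sp]][a]
      ssb[sp] <- x
    }
    list(W = W, M2 = M2, ssb = ssb, bio = bio)
  }

  out <- NULL
  for (k in seq_along(years)) {
    anomaly <- temps[k] - om$ref_temp
    q <- state_quants(N, anomaly)
    for (sp in spp) {
      s <- om$species[[sp]]
      catch <- 0
      for (a in 1:s$n_ages) {
        Za <- s$M1[a] + q$M2[[sp]][a] + s$selectivity[a] * F_applied[[sp]]
        if (s$selectivity[a] * F_applied[[sp]] > 0) {
          catch <- catch + (s$selectivity[a] * F_applied[[sp]] / Za) *
            (1 - exp(-Za)) * N[[sp]][a] * q$W[[sp]][a]
        }
      }
      out <- rbind(out, data.frame(year = years[k], species = sp,
                                   ssb = q$ssb[[sp]], catch = catch))
    }
    if (k < length(years)) {
      N_next <- list()
      for (sp in spp) {
        s <- om$species[[sp]]
        n <- numeric(s$n_ages)
        for (a in 1:s$n_ages) {
          Za <- s$M1[a] + q$M2[[sp]][a] + s$selectivity[a] * F_applied[[sp]]
          srv <- N[[sp]][a] * exp(-Za)
          if (a < s$n_ages) n[a + 1] <- n[a + 1] + srv
          else n[a] <- n[a] + srv
        }
        m <- toy$recruit_models[[sp]]
        B <- q$ssb[[sp]]
        covsum <- 0
        for (nm in names(m$betas)) {
          covsum <- covsum + m$betas[[nm]] *
            toy$forcing$indices[[nm]][k + 1]
        }
        n[1] <- exp(m$alpha - m$beta0 * B + log(B) + covsum)
        N_next[[sp]] <- n
      }
      N <- N_next
    }
  }
  rownames(out) <- NULL
  out
}
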