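# Shared fixtures, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# Full synthetic study bundle (cached per seed; building one takes ~0.3 s).
cached_fixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressWarnings(make_study_fixture(seed = seed))
  }
  .fixture_cache[[key]]
}

# Constant forcing covering `years` with all four standard indices.
const_series <- function(years, temp = 2, id = "persistence") {
  climate_series(id, years, list(
    bottom_temp = rep(temp, length(years)),
    cold_pool = rep(0.3, length(years)),
    zoop_spring = rep(4, length(years)),
    zoop_fall = rep(3, length(years))))
}

# Minimal one-species operating model with no predation, for solver and
# policy tests where inter-species coupling is noise.
single_species_om <- function() {
  sp <- species_config(
    name = "solo", n_ages = 6,
    maturity = c(0, 0.5, 1, 1, 1, 1),
    selectivity = c(0.2, 0.6, 1, 1, 1, 1),
    M1 = rep(0.3, 6),
    w_base = c(0.1, 0.3, 0.6, 0.9, 1.1, 1.3),
    thermal_w_sens = -0.02, init_recruits = 1000, hist_F = 0.1)
  om_config(list(sp), ref_temp = 2)
}

single_species_recruit <- function(sigma = 0) {
  list(solo = recruit_model(alpha = 1.0, beta0 = 1e-3,
                            betas = c(bottom_temp = -0.1), sigma = sigma))
}
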