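# Shared fixtures, all built in code.

# Two-region (one rural, one urban) miniature geography with modest
# populations so toy fits stay fast.
tiny_regions <- function(rate_m = 23, rate_f = 6) {
  list(
    droughtimpact:::.make_region("RuralA", FALSE, 600, 60000, 60000,
                                 rate_m, rate_f),
    droughtimpact:::.make_region("UrbanA", TRUE, 1200, 300000, 300000,
                                 rate_m, rate_f)
  )
}

tiny_config <- function(seed = 1, ...) {
  sim_config(regions = tiny_regions(), seed = seed, ...)
}

# Full simulated world (rain -> exposure -> temps -> pops -> counts)
# for a given config; returns everything a fit needs.
simulate_world <- function(cfg, lookback_years = 30) {
  rain <- generate_rainfall(cfg)
  exposure <- drought_counter(score_series(rain,
                                           lookback_years = lookback_years))
  temps <- generate_temperature(cfg, exposure)
  pops <- population_panel(cfg)
  suicides <- generate_suicides(exposure, temps, pops, cfg)
  urban_map <- vapply(cfg$regions, function(r) r$is_urban, logical(1))
  names(urban_map) <- vapply(cfg$regions, function(r) r$region_id,
                             character(1))
  list(config = cfg, rain = rain, exposure = exposure, temps = temps,
       pops = pops, suicides = suicides, urban_map = urban_map)
}

# Hand-built exposure series from a scripted counter run (for
# attribution and spell-accounting tests).
scripted_exposure <- function(counters, region_id = "R1",
                              start = c(1990, 1)) {
  idx <- droughtimpact:::month_index(start[1], start[2]) +
    seq_along(counters) - 1L
  data.frame(region_id = region_id, year = idx %/% 12L,
             month = idx %% 12L + 1L,
             score = ifelse(counters > 0, -2, 0),
             counter = as.integer(counters),
             full_drought = counters >= 7, X = log1p(counters),
             stringsAsFactors = FALSE)
}

# Counter sequence for a dry run of n months embedded in calm months.
run_counters <- function(n_dry, pre = 3, post = 3) {
  c(rep(0L, pre), seq_len(n_dry), rep(0L, post))
}
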