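# Generators: marginal moments, coupling, determinism, validation.

test_that("rainfall marginal mean matches the configured climatology", {
  rg <- droughtimpact:::.make_region("CW", FALSE, 605, 6e4, 6e4, 22, 6)
  cfg <- sim_config(regions = list(rg), start = c(1200, 1),
                    end = c(2033, 4), # 10,000 months
                    persistence_rho = 0, seed = 2)
  rain <- generate_rainfall(cfg)
  expect_equal(nrow(rain), 10000)
  # monthly sd = mu / sqrt(shape); 3 s.e. band on the annualized mean
  mu_m <- 605 / 12
  se_annual <- 12 * (mu_m / sqrt(cfg$rain_shape)) / sqrt(nrow(rain))
  expect_lt(abs(mean(rain$rain_mm) * 12 - 605), 3 * se_annual)
  expect_true(all(rain$rain_mm > 0))
})

test_that("large gamma shape collapses to the deterministic climatology", {
  rg <- droughtimpact:::.make_region("CW", FALSE, 600, 6e4, 6e4, 22, 6)
  cfg <- sim_config(regions = list(rg), start = c(1990, 1),
                    end = c(2009, 12), rain_shape = 1e6, seed = 4)
  rain <- generate_rainfall(cfg)
  cv <- sd(rain$rain_mm) / mean(rain$rain_mm)
  expect_lt(cv, 0.01)
})

test_that("rainfall persistence induces the configured autocorrelation", {
  rg <- droughtimpact:::.make_region("CW", FALSE, 600, 6e4, 6e4, 22, 6)
  cfg <- sim_config(regions = list(rg), start = c(1600, 1),
                    end = c(2016, 8), persistence_rho = 0.7, seed = 9)
  rain <- generate_rainfall(cfg)
  z <- qnorm(pgamma(rain$rain_mm, shape = cfg$rain_shape,
                    scale = 50 / cfg$rain_shape))
  r1 <- cor(z[-1], z[-length(z)])
  expect_lt(abs(r1 - 0.7), 0.05)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 123)
  expect_identical(generate_rainfall(cfg), generate_rainfall(cfg))
  cfg2 <- tiny_config(seed = 124)
  expect_false(identical(generate_rainfall(cfg), generate_rainfall(cfg2)))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_rainfall(tiny_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("region_spec validates its invariants", {
  keys <- as.vector(outer(c("10-29", "30-49", "50+"), c("male", "female"),
                          paste, sep = "."))
  pop <- setNames(rep(1000, 6), keys)
  rate <- setNames(rep(10, 6), keys)
  w <- rep(1 / 12, 12)
  expect_s3_class(region_spec("A", FALSE, 500, w, pop, rate), "region_spec")
  expect_error(region_spec("A", FALSE, 500, w * 2, pop, rate), "sum to 1")
  expect_error(region_spec("A", FALSE, 500, w, pop * 0, rate), "> 0")
  expect_error(sim_config(start = c(2000, 1), end = c(1999, 1)), "precede")
  expect_error(sim_config(persistence_rho = 1), "persistence_rho")
})

test_that("temperature anomalies have the requested drought coupling", {
  counters <- rep(c(rep(0L, 10), 1:14), length.out = 10000)
  ex <- scripted_exposure(counters, start = c(1200, 1))
  cfg0 <- sim_config(regions = tiny_regions()[1], start = c(1200, 1),
                     end = c(2033, 4), temp_coupling = 0, seed = 5)
  t0 <- generate_temperature(cfg0, ex)
  expect_lt(abs(cor(t0$tmax_anomaly_c, ex$counter)), 0.05)
  expect_lt(abs(mean(t0$tmax_anomaly_c)), 0.05)
  expect_lt(abs(sd(t0$tmax_anomaly_c) - cfg0$temp_sd), 0.05)

  cfg3 <- sim_config(regions = tiny_regions()[1], start = c(1200, 1),
                     end = c(2033, 4), temp_coupling = 0.3, seed = 5)
  t3 <- generate_temperature(cfg3, ex)
  expect_lt(abs(cor(t3$tmax_anomaly_c, ex$counter) - 0.3), 0.05)

  cfg_z <- sim_config(regions = tiny_regions()[1], start = c(1200, 1),
                      end = c(2033, 4), temp_sd = 0, seed = 5)
  tz <- generate_temperature(cfg_z, ex)
  expect_equal(unique(tz$tmax_anomaly_c), 0)
})

test_that("population interpolation is linear between January censuses", {
  cens <- data.frame(year = c(1971, 1976), region_id = "A",
                     age_group = "30-49", sex = "male", pop = c(100, 160))
  pp <- interpolate_population(cens, c(1970, 1), c(1978, 12))
  expect_equal(pp$pop[pp$year == 1973 & pp$month == 7], 130)
  # census values reproduced exactly; constant extrapolation outside
  expect_equal(pp$pop[pp$year == 1971 & pp$month == 1], 100)
  expect_equal(pp$pop[pp$year == 1976 & pp$month == 1], 160)
  expect_equal(unique(pp$pop[pp$year == 1970]), 100)
  expect_equal(unique(pp$pop[pp$year %in% 1977:1978]), 160)

  flat <- data.frame(year = c(1971, 1976), region_id = "A",
                     age_group = "30-49", sex = "male", pop = 67747)
  pf <- interpolate_population(flat, c(1971, 1), c(1976, 12))
  expect_equal(unique(pf$pop), 67747)

  expect_error(interpolate_population(cens[1, ], c(1970, 1), c(1978, 12)),
               "at least 2")
  dup <- rbind(cens, cens[1, ])
  expect_error(interpolate_population(dup, c(1970, 1), c(1978, 12)),
               "duplicate")
})

test_that("suicide counts hit the configured expectation when beta = 0", {
  # one rural region at the Central West male scale: rate 22/100k on
  # 67,747 males over 29 years -> about 432 expected deaths
  rg <- droughtimpact:::.make_region("CW", FALSE, 605, 67747, 67248, 22, 6)
  betas <- default_drought_betas()
  betas$beta <- 0
  cfg <- sim_config(regions = list(rg), start = c(1971, 1),
                    end = c(1999, 12), drought_betas = betas,
                    season_amp = 0, temp_coef = 0, seed = 6)
  grid <- droughtimpact:::ym_grid(cfg$start, cfg$end)
  ex <- scripted_exposure(rep(0L, nrow(grid)), region_id = "CW",
                          start = cfg$start)
  temps <- generate_temperature(cfg, ex)
  pops <- population_panel(cfg)
  sui <- generate_suicides(ex, temps, pops, cfg)
  males <- sui[sui$sex == "male", ]
  expected <- 29 * 12 * (22 / 1e5 / 12) * 67747
  expect_lt(abs(sum(males$count) - expected), 3 * sqrt(expected))
})

test_that("a drought slope of ln 2 doubles counts at X = 1", {
  rg <- droughtimpact:::.make_region("R", FALSE, 600, 1.2e6, 1.2e6, 50, 50)
  betas <- default_drought_betas()
  betas$beta <- log(2)
  mk_counts <- function(x, seed) {
    cfg <- sim_config(regions = list(rg), start = c(1990, 1),
                      end = c(2003, 12), drought_betas = betas,
                      season_amp = 0, temp_coef = 0, seed = seed)
    grid <- droughtimpact:::ym_grid(cfg$start, cfg$end)
    counters <- rep(if (x == 1) exp(1) - 1 else 0, nrow(grid))
    ex <- scripted_exposure(rep(0L, nrow(grid)), region_id = "R",
                            start = cfg$start)
    ex$X <- rep(x, nrow(grid)) # X forced directly
    temps <- generate_temperature(cfg, ex)
    sum(generate_suicides(ex, temps, population_panel(cfg), cfg)$count)
  }
  n1 <- mk_counts(1, 8)
  n0 <- mk_counts(0, 8)
  # ~100k expected events per arm: ratio within 3 relative s.e.
  expect_lt(abs(n1 / n0 - 2), 3 * 2 * sqrt(1 / n1 + 1 / n0))
})

test_that("suicide generator enforces preconditions", {
  w <- simulate_world(tiny_config(seed = 2))
  bad_pops <- w$pops
  bad_pops$pop[1] <- 0
  expect_error(generate_suicides(w$exposure, w$temps, bad_pops, w$config),
               "population")
  betas <- w$config$drought_betas[-1, ]
  expect_error(sim_config(regions = tiny_regions(), drought_betas = betas),
               "nrow")
})

test_that("delta tables ramp linearly and are deterministic", {
  spec0 <- list(gcm = "G", rcp = "R", endpoint_pct = 0, regions = "A")
  d0 <- generate_deltas(spec0)
  expect_equal(unique(d0$pct_change), 0)
  expect_equal(nrow(d0), 12 * length(2006:2099))

  spec <- list(gcm = "G", rcp = "R", endpoint_pct = -20, regions = "A")
  d <- generate_deltas(spec)
  expect_equal(unique(d$pct_change[d$year == 2052]),
               -20 * (2052 - 2006) / (2099 - 2006),
               tolerance = 1e-12)
  expect_equal(unique(d$pct_change[d$year == 2099]), -20)
  expect_identical(d, generate_deltas(spec)) # no randomness
  expect_error(generate_deltas(list(gcm = "G", rcp = "R",
                                    endpoint_pct = -100, regions = "A")),
               "-100")
})
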