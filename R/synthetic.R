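# Synthetic panel generators.
#
# Emulates the statistical structure the downstream analysis assumes:
# seasonal gamma-distributed monthly rainfall with AR(1) persistence on
# normal-score anomalies (so multi-month dry spells occur), temperature
# anomalies optionally weakly coupled to drought, census-interpolated
# populations, and Poisson suicide counts generated as the exact
# generative inverse of the fitted exposure-response model.

#' Region specification
#'
#' @param region_id short label.
#' @param is_urban logical; urban regions get the urban drought slopes.
#' @param annual_rain_mm long-run mean annual rainfall (mm).
#' @param monthly_rain_weights 12 non-negative weights summing to 1;
#'   month m's mean rainfall is `annual_rain_mm * weight[m]`.
#' @param pop_by_stratum named numeric, one positive entry per
#'   `age.sex` stratum (names like `"30-49.male"`).
#' @param baseline_suicide_rate named numeric, deaths per 100,000
#'   person-years per stratum (same names).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(region_id, is_urban, annual_rain_mm,
                        monthly_rain_weights = rep(1 / 12, 12),
                        pop_by_stratum, baseline_suicide_rate) {
  stopifnot(length(monthly_rain_weights) == 12,
            all(monthly_rain_weights >= 0),
            annual_rain_mm > 0)
  if (abs(sum(monthly_rain_weights) - 1) > 1e-9) {
    stop("monthly_rain_weights must sum to 1", call. = FALSE)
  }
  keys <- as.vector(outer(AGE_GROUPS, SEXES, paste, sep = "."))
  if (!all(keys %in% names(pop_by_stratum))) {
    stop("pop_by_stratum must name every age.sex stratum", call. = FALSE)
  }
  if (any(pop_by_stratum[keys] <= 0)) stop("populations must be > 0", call. = FALSE)
  if (!all(keys %in% names(baseline_suicide_rate)) ||
      any(baseline_suicide_rate[keys] < 0)) {
    stop("baseline_suicide_rate must be >= 0 for every stratum", call. = FALSE)
  }
  structure(list(region_id = region_id, is_urban = isTRUE(is_urban),
                 annual_rain_mm = annual_rain_mm,
                 monthly_rain_weights = monthly_rain_weights,
                 pop_by_stratum = pop_by_stratum[keys],
                 baseline_suicide_rate = baseline_suicide_rate[keys]),
            class = "region_spec")
}

# Helper: equal age split of a per-sex population, same rate all ages.
.make_region <- function(id, urban, rain_mm, pop_m, pop_f, rate_m, rate_f) {
  keys <- as.vector(outer(AGE_GROUPS, SEXES, paste, sep = "."))
  pop <- c(rep(pop_m / 3, 3), rep(pop_f / 3, 3))
  rate <- c(rep(rate_m, 3), rep(rate_f, 3))
  names(pop) <- names(rate) <- keys
  region_spec(id, urban, rain_mm, pop_by_stratum = pop,
              baseline_suicide_rate = rate)
}

#' Default panel geography: 8 rural and 3 urban regions
#'
#' Magnitudes (annual rainfall, per-sex populations and male suicide
#' rates) follow the NSW statistical-division descriptive statistics
#' for 1971-1999; per-sex populations are split equally across the
#' three age groups. Female rates are the male rates scaled by the
#' overall female/male rate ratio (0.24), so baseline log rates
#' decompose exactly into region + sex main effects: the generative
#' world stays inside the span of the regression it feeds (crude
#' female rates remain at the observed 5-7 per 100,000 magnitude).
#' Urban coastal rainfall, which the historical tables do not report,
#' is set near 1100-1200 mm.
#'
#' @return list of [region_spec()] objects.
#' @export
default_regions <- function() {
  fm <- 0.24 # female/male rate ratio
  mk <- function(id, urban, rain, pm, pf, rate_m) {
    .make_region(id, urban, rain, pm, pf, rate_m, rate_m * fm)
  }
  list(
    mk("CentralWest",    FALSE,  605,   67747,   67248, 22),
    mk("MidNorthCoast",  FALSE, 1309,   83073,   85065, 22),
    mk("Murray",         FALSE,  410,   42276,   41213, 24),
    mk("Murrumbidgee",   FALSE,  516,   58718,   57488, 24),
    mk("NorthFarWest",   FALSE,  371,   57572,   55804, 30),
    mk("Northern",       FALSE,  760,   72557,   72349, 23),
    mk("RichmondTweed",  FALSE, 1405,   62366,   64221, 24),
    mk("SouthEastern",   FALSE,  790,   64079,   62123, 25),
    mk("Sydney",         TRUE,  1200, 1424283, 1473113, 21),
    mk("Hunter",         TRUE,  1100,  203210,  205637, 21),
    mk("Illawarra",      TRUE,  1200,  132224,  131181, 21)
  )
}

#' Default drought slopes per age x sex x rural/urban stratum
#'
#' Rural males 30-49 get `log(1.14)/1.07` and rural females 30-49
#' `log(0.86)/1.07` (the slopes implied by the reported relative risks
#' per 1.07-unit IQR of log drought duration); rural males 10-29 a
#' smaller positive slope; rural females 50+ a small negative slope.
#' All urban slopes and the remaining rural slopes are zero.
#'
#' @return data frame `age_group`, `sex`, `is_urban`, `beta` (12 rows).
#' @export
default_drought_betas <- function() {
  b <- expand.grid(age_group = AGE_GROUPS, sex = SEXES,
                   is_urban = c(FALSE, TRUE), stringsAsFactors = FALSE)
  b$beta <- 0
  set_beta <- function(b, age, sex, urban, val) {
    b$beta[b$age_group == age & b$sex == sex & b$is_urban == urban] <- val
    b
  }
  b <- set_beta(b, "30-49", "male",   FALSE, log(1.14) / 1.07)
  b <- set_beta(b, "30-49", "female", FALSE, log(0.86) / 1.07)
  b <- set_beta(b, "10-29", "male",   FALSE, log(1.10) / 1.07)
  b <- set_beta(b, "50+",   "female", FALSE, log(0.95) / 1.07)
  b
}

#' Simulation configuration
#'
#' @param regions list of [region_spec()]; default [default_regions()].
#' @param start,end `c(year, month)` panel endpoints (inclusive).
#' @param rain_shape gamma shape of monthly rainfall (> 0). Smaller is
#'   more skewed; 2 gives realistic monthly rainfall skew.
#' @param persistence_rho AR(1) coefficient on normal-score rainfall
#'   anomalies, in `[0, 1)`. Controls dry-spell lengths; the default
#'   0.85 is calibrated once so that stationary synthetic rainfall
#'   reproduces the descriptive drought statistics of rural NSW
#'   divisions (about 7 full droughts per 29 years, mean full-drought
#'   duration 9-12 months). The high monthly coefficient stands in for
#'   ENSO-driven interannual persistence that a monthly AR(1) cannot
#'   otherwise express.
#' @param temp_sd standard deviation of temperature anomalies (deg C).
#' @param temp_coupling target Pearson correlation between temperature
#'   anomalies and the drought counter (0 disables coupling).
#' @param drought_betas data frame as [default_drought_betas()].
#' @param trend_coef linear log-rate trend per decade.
#' @param season_amp amplitude of the log-rate seasonal cosine.
#' @param season_phase calendar month of the seasonal peak.
#' @param temp_coef log-rate change per deg C temperature anomaly.
#' @param seed master seed; all stage streams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(regions = default_regions(),
                       start = c(1940, 1), end = c(2007, 12),
                       rain_shape = 2, persistence_rho = 0.85,
                       temp_sd = 1, temp_coupling = 0.3,
                       drought_betas = default_drought_betas(),
                       trend_coef = 0, season_amp = 0.1, season_phase = 7,
                       temp_coef = 0.01, seed = 1L) {
  stopifnot(rain_shape > 0, persistence_rho >= 0, persistence_rho < 1,
            temp_sd >= 0)
  if (month_index(start[1], start[2]) >= month_index(end[1], end[2])) {
    stop("start must precede end", call. = FALSE)
  }
  need <- c("age_group", "sex", "is_urban", "beta")
  stopifnot(all(need %in% names(drought_betas)), nrow(drought_betas) == 12)
  structure(list(regions = regions, start = start, end = end,
                 rain_shape = rain_shape, persistence_rho = persistence_rho,
                 temp_sd = temp_sd, temp_coupling = temp_coupling,
                 drought_betas = drought_betas, trend_coef = trend_coef,
                 season_amp = season_amp, season_phase = season_phase,
                 temp_coef = temp_coef, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a monthly rainfall panel
#'
#' Each region-month is gamma distributed with shape `rain_shape` and
#' month-specific scale `annual_rain_mm * weight[m] / rain_shape`, so
#' the marginal monthly mean equals the configured climatology.
#' Persistence is induced by an AR(1) process on standard-normal
#' anomalies mapped through the gamma quantile function, which keeps
#' the marginals exact while making multi-month dry spells likely.
#'
#' @param config a [sim_config()].
#' @return data frame `region_id`, `year`, `month`, `rain_mm`.
#' @export
generate_rainfall <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- ym_grid(config$start, config$end)
  n <- nrow(grid)
  rho <- config$persistence_rho
  shape <- config$rain_shape
  out <- vector("list", length(config$regions))
  withr_seed <- derive_seed(config$seed, "rainfall")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  for (i in seq_along(config$regions)) {
    rg <- config$regions[[i]]
    e <- stats::rnorm(n)
    z <- numeric(n)
    z[1] <- e[1]
    if (n > 1) {
      sc <- sqrt(1 - rho^2)
      for (t in 2:n) z[t] <- rho * z[t - 1] + sc * e[t]
    }
    u <- stats::pnorm(z)
    mu <- rg$annual_rain_mm * rg$monthly_rain_weights[grid$month]
    rain <- stats::qgamma(u, shape = shape, scale = mu / shape)
    out[[i]] <- data.frame(region_id = rg$region_id, year = grid$year,
                           month = grid$month, rain_mm = rain,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Save/restore global RNG state so generators do not perturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a rainfall panel from a scripted series
#'
#' Deterministic helper for state-machine unit tests: wraps a verbatim
#' monthly rainfall vector into a panel starting at `start`.
#'
#' @param rain_mm numeric vector of monthly rainfall values.
#' @param region_id region label.
#' @param start `c(year, month)` of the first value.
#' @return rainfall panel data frame.
#' @export
scripted_rainfall <- function(rain_mm, region_id = "scripted",
                              start = c(1940, 1)) {
  idx <- month_index(start[1], start[2]) + seq_along(rain_mm) - 1L
  data.frame(region_id = region_id, year = idx %/% 12L,
             month = idx %% 12L + 1L, rain_mm = rain_mm,
             stringsAsFactors = FALSE)
}

#' Generate monthly maximum-temperature anomalies
#'
#' Mean-zero anomalies with standard deviation `temp_sd`, optionally
#' linearly coupled to the drought counter so that the sample Pearson
#' correlation approximates `temp_coupling`.
#'
#' @param config a [sim_config()].
#' @param exposure exposure series aligned with the config's
#'   region-months (may cover a subset of months; anomalies are
#'   generated on the exposure grid).
#' @return data frame `region_id`, `year`, `month`, `tmax_anomaly_c`.
#' @export
generate_temperature <- function(config, exposure) {
  stopifnot(inherits(config, "sim_config"),
            all(c("region_id", "year", "month", "counter") %in% names(exposure)))
  check_contiguous(exposure)
  rho <- config$temp_coupling
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "temperature"))
  parts <- lapply(split(exposure, exposure$region_id), function(d) {
    d <- d[order(month_index(d$year, d$month)), , drop = FALSE]
    n <- nrow(d)
    eps <- stats::rnorm(n)
    if (rho != 0 && stats::sd(d$counter) > 0) {
      cstd <- as.numeric(scale(d$counter))
      a <- rho * cstd + sqrt(1 - rho^2) * eps
    } else {
      a <- eps
    }
    data.frame(region_id = d$region_id, year = d$year, month = d$month,
               tmax_anomaly_c = config$temp_sd * a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Interpolate stratum populations between censuses
#'
#' Monthly populations linear between adjacent census counts (anchored
#' at January of each census year), reproducing the census values
#' exactly at census dates and held constant outside the census range.
#'
#' @param censuses data frame `year`, `region_id`, `age_group`, `sex`,
#'   `pop`; at least two distinct census years per stratum.
#' @param start,end `c(year, month)` endpoints of the output grid.
#' @return data frame `region_id`, `year`, `month`, `age_group`, `sex`,
#'   `pop`.
#' @export
interpolate_population <- function(censuses, start, end) {
  need <- c("year", "region_id", "age_group", "sex", "pop")
  stopifnot(all(need %in% names(censuses)))
  grid <- ym_grid(start, end)
  tgrid <- month_index(grid$year, grid$month)
  key <- interaction(censuses$region_id, censuses$age_group, censuses$sex,
                     drop = TRUE)
  parts <- lapply(split(censuses, key), function(cd) {
    if (nrow(cd) < 2L) stop("need at least 2 census points", call. = FALSE)
    if (anyDuplicated(cd$year)) stop("duplicate census years", call. = FALSE)
    cd <- cd[order(cd$year), , drop = FALSE]
    ct <- month_index(cd$year, rep(1L, nrow(cd)))
    pop <- stats::approx(ct, cd$pop, xout = tgrid, rule = 2)$y
    data.frame(region_id = cd$region_id[1], year = grid$year,
               month = grid$month, age_group = cd$age_group[1],
               sex = cd$sex[1], pop = pop, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Constant-population panel from region specifications
#'
#' Convenience wrapper: two identical pseudo-censuses at the grid
#' endpoints, giving each stratum its `pop_by_stratum` value in every
#' month.
#'
#' @param config a [sim_config()].
#' @return population panel as from [interpolate_population()].
#' @export
population_panel <- function(config) {
  rows <- list()
  for (rg in config$regions) {
    for (k in names(rg$pop_by_stratum)) {
      ag <- sub("\\.(male|female)$", "", k)
      sx <- sub("^.*\\.", "", k)
      rows[[length(rows) + 1L]] <- data.frame(
        year = c(config$start[1], config$end[1] + 1L),
        region_id = rg$region_id, age_group = ag, sex = sx,
        pop = rg$pop_by_stratum[[k]], stringsAsFactors = FALSE)
    }
  }
  interpolate_population(do.call(rbind, rows), config$start, config$end)
}

#' Generate Poisson suicide counts from the exposure-response model
#'
#' The exact generative inverse of the fitted model: counts are Poisson
#' with log mean equal to the stratum intercept (baseline rate), plus
#' `beta * X` for the stratum's drought slope, a linear trend, a cosine
#' season, a temperature-anomaly term and the log-population offset.
#'
#' @param exposure exposure series (provides `X` per region-month).
#' @param temps temperature panel aligned with `exposure`.
#' @param pops population panel covering the exposure months.
#' @param config a [sim_config()] (slopes, trend/season/temperature
#'   coefficients, baseline rates, seed).
#' @return data frame `region_id`, `year`, `month`, `age_group`, `sex`,
#'   `count`, `pop`, plus the `X` and `tmax_anomaly_c` used.
#' @export
generate_suicides <- function(exposure, temps, pops, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(pops$pop <= 0)) stop("negative or zero population", call. = FALSE)
  ex <- merge(exposure[, c("region_id", "year", "month", "X")],
              temps[, c("region_id", "year", "month", "tmax_anomaly_c")],
              by = c("region_id", "year", "month"))
  if (nrow(ex) != nrow(exposure)) stop("misaligned panels", call. = FALSE)
  dat <- merge(ex, pops, by = c("region_id", "year", "month"))
  if (nrow(dat) != nrow(ex) * 6L) stop("population panel incomplete", call. = FALSE)
  urban <- vapply(config$regions, function(r) r$is_urban, logical(1))
  names(urban) <- vapply(config$regions, function(r) r$region_id, character(1))
  rates <- do.call(rbind, lapply(config$regions, function(r) {
    data.frame(region_id = r$region_id,
               stratum = names(r$baseline_suicide_rate),
               rate = unname(r$baseline_suicide_rate),
               stringsAsFactors = FALSE)
  }))
  dat$stratum <- paste(dat$age_group, dat$sex, sep = ".")
  dat <- merge(dat, rates, by = c("region_id", "stratum"))
  b <- config$drought_betas
  bk <- stratum_key(b$age_group, b$sex, b$is_urban)
  beta_map <- stats::setNames(b$beta, bk)
  dk <- stratum_key(dat$age_group, dat$sex, urban[dat$region_id])
  if (anyNA(beta_map[dk])) stop("missing stratum drought coefficient", call. = FALSE)
  t0 <- month_index(config$start[1], config$start[2])
  tdec <- (month_index(dat$year, dat$month) - t0) / 120 # decades
  # Seasonal log-rate curve: a cosine of amplitude season_amp peaked at
  # season_phase, projected onto the df = 4 cyclic spline block the
  # model fits, so the generative season lies exactly in the fitted
  # span (the simulation is the generative inverse of the model).
  B12 <- season_basis_cc(1:12, df = 4)
  target <- config$season_amp *
    cos(2 * pi * ((1:12) - config$season_phase) / 12)
  scoef <- qr.coef(qr(B12), target)
  season <- as.numeric(season_basis_cc(dat$month, df = 4) %*% scoef)
  logmu <- log(dat$rate / 1e5 / 12) +
    beta_map[dk] * dat$X +
    config$trend_coef * tdec +
    season +
    config$temp_coef * dat$tmax_anomaly_c +
    log(dat$pop)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "suicides"))
  ord <- order(dat$region_id, dat$age_group, dat$sex,
               month_index(dat$year, dat$month))
  dat <- dat[ord, , drop = FALSE]
  logmu <- logmu[ord]
  dat$count <- stats::rpois(nrow(dat), exp(logmu))
  rownames(dat) <- NULL
  dat[, c("region_id", "year", "month", "age_group", "sex", "count",
          "pop", "X", "tmax_anomaly_c")]
}

#' Generate a scenario delta table
#'
#' Deterministic monthly rainfall percentage-change trajectories per
#' GCM x RCP x region, ramping from 0 at the projection start to the
#' configured endpoint by the final year.
#'
#' @param scenario list with `gcm`, `rcp`, `endpoint_pct` (single value
#'   or named per region), `regions` (character), and optional
#'   `start_year` (default 2006), `end_year` (default 2099),
#'   `shape` (`"linear"`, the only implemented ramp).
#' @return data frame `gcm`, `rcp`, `region_id`, `year`, `month`,
#'   `pct_change`.
#' @export
generate_deltas <- function(scenario) {
  start <- scenario$start_year %||% 2006L
  end <- scenario$end_year %||% 2099L
  shape <- scenario$shape %||% "linear"
  stopifnot(shape == "linear", end > start)
  ep <- scenario$endpoint_pct
  regions <- scenario$regions
  if (length(ep) == 1L && is.null(names(ep))) {
    ep <- stats::setNames(rep(ep, length(regions)), regions)
  }
  if (any(ep <= -100)) stop("endpoint_pct must be > -100", call. = FALSE)
  grid <- expand.grid(month = 1:12, year = start:end,
                      region_id = regions, stringsAsFactors = FALSE)
  frac <- (grid$year - start) / (end - start)
  data.frame(gcm = scenario$gcm, rcp = scenario$rcp,
             region_id = grid$region_id, year = grid$year,
             month = grid$month,
             pct_change = unname(ep[grid$region_id]) * frac,
             stringsAsFactors = FALSE)
}
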