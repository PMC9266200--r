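# End-to-end orchestration and reporting.

#' Read / write the pipeline's CSV artifacts
#'
#' Thin wrappers around [utils::read.csv()] / [utils::write.csv()] that
#' validate the expected columns, so every writer's output round-trips
#' through its reader.
#'
#' @param path file path.
#' @param df data frame to write.
#' @param columns required column names.
#' @return the data frame (readers), invisibly the path (writers).
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
read_panel_csv <- function(path, columns) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname panel_io
#' @export
write_panel_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a model fit as JSON
#'
#' @param fit a `drought_fit`.
#' @param path JSON file path.
#' @return `write_fit_json`: the path, invisibly. `read_fit_json`: a
#'   list with the coefficient names, estimates, SEs, covariance and
#'   diagnostics (not a full refittable object).
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              vcov = unname(fit$vcov), # row-major via jsonlite matrix default
              deviance = fit$deviance, df_residual = fit$df_residual,
              pearson = fit$pearson, dispersion = dispersion(fit),
              n = fit$n, period = fit$period,
              time_df = fit$time_df, month_df = fit$month_df,
              seasonal = fit$seasonal)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$se <- unlist(obj$se)
  obj
}

#' Descriptive summary tables
#'
#' Weather table per region (annual rainfall mean, mean temperature
#' anomaly, full-drought count, mean and maximum reported duration)
#' and a suicide/population table per region x sex (total suicides,
#' mean annual suicides, mean annual population, crude rate per
#' 100,000 person-years rounded to integer).
#'
#' @param rain,temps,exposure,suicides,pops panels as produced by the
#'   generators / index (suicide panel must carry `pop`, or pass
#'   `pops`).
#' @param period `c(first_year, last_year)`.
#' @return list `weather`, `suicide`.
#' @export
descriptive_tables <- function(rain, temps, exposure, suicides,
                               pops = NULL, period = c(1971, 1999)) {
  yr <- function(d) d$year >= period[1] & d$year <= period[2]
  if (!any(yr(rain))) stop("empty period", call. = FALSE)
  r <- rain[yr(rain), ]
  rain_annual <- stats::aggregate(rain_mm ~ region_id + year, data = r, sum)
  rain_mean <- stats::aggregate(rain_mm ~ region_id, data = rain_annual, mean)
  t <- temps[yr(temps), ]
  temp_mean <- stats::aggregate(tmax_anomaly_c ~ region_id, data = t, mean)
  dr <- summarize_droughts(exposure, period = period)$summary
  weather <- merge(rain_mean, temp_mean, by = "region_id", all = TRUE)
  weather <- merge(weather, dr, by = "region_id", all.x = TRUE)
  weather$n_spells[is.na(weather$n_spells)] <- 0L
  names(weather)[names(weather) == "rain_mm"] <- "rain_annual_mean_mm"
  names(weather)[names(weather) == "tmax_anomaly_c"] <- "tmax_anomaly_mean_c"
  names(weather)[names(weather) == "n_spells"] <- "n_full_droughts"

  s <- suicides[yr(suicides), ]
  if (is.null(pops)) {
    stopifnot("pop" %in% names(s))
    p <- s
  } else {
    p <- pops[yr(pops), ]
  }
  tot <- stats::aggregate(count ~ region_id + sex, data = s, sum)
  names(tot)[names(tot) == "count"] <- "total_suicides"
  nyears <- period[2] - period[1] + 1
  tot$mean_annual_suicides <- tot$total_suicides / nyears
  # mean annual population per sex: sum strata within month, average months
  pm <- stats::aggregate(pop ~ region_id + sex + year + month, data = p, sum)
  pmean <- stats::aggregate(pop ~ region_id + sex, data = pm, mean)
  names(pmean)[names(pmean) == "pop"] <- "mean_annual_population"
  suic <- merge(tot, pmean, by = c("region_id", "sex"))
  suic$rate_per_100k <- round(1e5 * suic$mean_annual_suicides /
                              suic$mean_annual_population)
  list(weather = weather, suicide = suic)
}

# Default run configuration; a user config (list or YAML file) is
# merged over these values.
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("droughtimpact_run_"),
    simulate = TRUE,
    inputs = list(), # rain/temps/pops/suicides CSV paths when simulate = FALSE
    regions = NULL, # NULL = default_regions()
    sim = list(start = c(1940, 1), end = c(2007, 12)),
    lookback_years = 30,
    fit_period = c(1970, 1, 2007, 10),
    historical_period = c(1971, 1999),
    scenario_period = c(2000, 2099),
    baseline_climate = c(1986, 2005),
    mc_iterations = 1000,
    iqr_months = "all",
    time_df = 3, month_df = 4, seasonal = "cc",
    scenarios = list(
      list(gcm = "GCM-DRY", rcp = "RCP8.5", endpoint_pct = -20),
      list(gcm = "GCM-DRY", rcp = "RCP4.5", endpoint_pct = -12),
      list(gcm = "GCM-WET", rcp = "RCP4.5", endpoint_pct = 5)
    )
  )
}

# Tiny FNV-style hash of a deparsed object, for the run manifest.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((h %% 2^24) * 16777619 + ch) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> drought index -> model fit -> scenario
#' projection -> attribution -> descriptive tables, writing every stage
#' artifact plus a manifest (config hash, derived seeds, package
#' version) to `out_dir`. All randomness derives from the master seed,
#' so the same config reproduces bit-identically.
#'
#' @param config list overriding [default_run_config()] entries, or a
#'   path to a YAML file with the same structure.
#' @return (invisibly) list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  # unnamed lists (scenarios, regions) replace rather than merge
  for (nm in c("scenarios", "regions")) {
    if (!is.null(config[[nm]])) cfg[[nm]] <- config[[nm]]
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_stage(name, " done in ", round(proc.time()[3] - t0, 1), "s")
    res
  }

  sc <- sim_config(regions = cfg$regions %||% default_regions(),
                   start = cfg$sim$start, end = cfg$sim$end, seed = cfg$seed)
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", list(config = sc, rain = generate_rainfall(sc)))
    exposure <- stage("drought-index", {
      drought_counter(score_series(sim$rain,
                                   lookback_years = cfg$lookback_years))
    })
    temps <- stage("temperature", generate_temperature(sim$config, exposure))
    pops <- stage("population", population_panel(sim$config))
    suicides <- stage("suicides",
                      generate_suicides(exposure, temps, pops, sim$config))
  } else {
    sim <- stage("inputs", {
      for (nm in c("rain", "temps", "pops", "suicides")) {
        pth <- cfg$inputs[[nm]]
        if (is.null(pth) || !file.exists(pth)) {
          stop("simulate = FALSE and input '", nm, "' missing: ",
               pth %||% "<unset>", call. = FALSE)
        }
      }
      rain <- read_panel_csv(cfg$inputs$rain,
                             c("region_id", "year", "month", "rain_mm"))
      list(config = sc, rain = rain)
    })
    exposure <- stage("drought-index", {
      drought_counter(score_series(sim$rain,
                                   lookback_years = cfg$lookback_years))
    })
    temps <- stage("temperature", read_panel_csv(cfg$inputs$temps,
      c("region_id", "year", "month", "tmax_anomaly_c")))
    pops <- stage("population", read_panel_csv(cfg$inputs$pops,
      c("region_id", "year", "month", "age_group", "sex", "pop")))
    suicides <- stage("suicides", {
      s <- read_panel_csv(cfg$inputs$suicides,
        c("region_id", "year", "month", "age_group", "sex", "count"))
      if (!"pop" %in% names(s)) {
        s <- merge(s, pops, by = c("region_id", "year", "month",
                                   "age_group", "sex"))
      }
      s
    })
  }
  urban_map <- vapply(sc$regions, function(r) r$is_urban, logical(1))
  names(urban_map) <- vapply(sc$regions, function(r) r$region_id,
                             character(1))
  fit <- stage("fit", {
    fit_poisson(suicides, exposure, temps, urban_map,
                period = cfg$fit_period, time_df = cfg$time_df,
                month_df = cfg$month_df, seasonal = cfg$seasonal)
  })
  scen <- stage("project", {
    regions <- names(urban_map)
    out <- list()
    for (s in cfg$scenarios) {
      s$regions <- regions
      s$end_year <- s$end_year %||% cfg$scenario_period[2]
      deltas <- generate_deltas(s)
      series <- apply_deltas(sim$rain, deltas, baseline = cfg$baseline_climate)
      ex <- scenario_exposure(series, lookback_years = cfg$lookback_years)
      out[[paste(s$gcm, s$rcp, sep = ".")]] <-
        list(deltas = deltas, series = series, exposure = ex)
    }
    out
  })
  attrib <- stage("attribute", {
    hist <- historical_monthly_means(suicides, period = cfg$historical_period)
    rural <- names(urban_map)[!urban_map]
    results <- list()
    for (ag in AGE_GROUPS) {
      for (sx in SEXES) {
        h <- hist[hist$region_id %in% rural & hist$age_group == ag &
                  hist$sex == sx, ]
        seed_s <- derive_seed(cfg$seed, paste("mc", ag, sx))
        r0 <- monte_carlo_ci(fit, exposure, h, cfg$historical_period,
                             age_group = ag, sex = sx, is_urban = FALSE,
                             n = cfg$mc_iterations, seed = seed_s)
        results[[length(results) + 1L]] <-
          c(list(age_group = ag, sex = sx, scenario = "historical"), r0)
        for (nm in names(scen)) {
          rs <- monte_carlo_ci(fit, scen[[nm]]$exposure, h,
                               cfg$scenario_period,
                               age_group = ag, sex = sx, is_urban = FALSE,
                               n = cfg$mc_iterations, seed = seed_s)
          results[[length(results) + 1L]] <-
            c(list(age_group = ag, sex = sx, scenario = nm), rs)
        }
      }
    }
    results
  })
  tables <- stage("report", {
    an_table <- do.call(rbind, lapply(attrib, function(r) {
      data.frame(age_group = r$age_group, sex = r$sex, scenario = r$scenario,
                 an_per_annum = r$an, ci_low = r$ci_low, ci_high = r$ci_high,
                 mc_median = r$mc_median, stringsAsFactors = FALSE)
    }))
    cmp <- compare_scenarios(attrib)
    durations <- duration_summary_by_scenario(
      c(list(historical = exposure),
        stats::setNames(lapply(scen, `[[`, "exposure"), names(scen))),
      periods = list(historical = cfg$historical_period,
                     scenario = cfg$scenario_period))
    desc <- descriptive_tables(sim$rain, temps, exposure, suicides,
                               period = cfg$historical_period)
    list(an = an_table, comparison = cmp, durations = durations,
         descriptive = desc)
  })

  od <- cfg$out_dir
  write_panel_csv(sim$rain, file.path(od, "rainfall.csv"))
  write_panel_csv(exposure, file.path(od, "exposure.csv"))
  write_panel_csv(temps, file.path(od, "temperature.csv"))
  write_panel_csv(pops, file.path(od, "population.csv"))
  write_panel_csv(suicides, file.path(od, "suicides.csv"))
  write_fit_json(fit, file.path(od, "fit.json"))
  write_panel_csv(tables$an, file.path(od, "attributable_numbers.csv"))
  write_panel_csv(tables$durations, file.path(od, "durations.csv"))
  write_panel_csv(tables$descriptive$weather, file.path(od, "table1_weather.csv"))
  write_panel_csv(tables$descriptive$suicide, file.path(od, "table2_suicide.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("droughtimpact")),
    r_version = as.character(getRversion()),
    master_seed = cfg$seed,
    stage_seeds = list(
      rainfall = derive_seed(cfg$seed, "rainfall"),
      temperature = derive_seed(cfg$seed, "temperature"),
      suicides = derive_seed(cfg$seed, "suicides")
    ),
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, rain = sim$rain, exposure = exposure,
                 temps = temps, pops = pops, suicides = suicides, fit = fit,
                 scenarios = scen, attribution = attrib, tables = tables,
                 manifest = manifest, out_dir = od))
}
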