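# Delta-change scenario projection.
#
# Future monthly rainfall is built by scaling the observed 1986-2005
# baseline climate with GCM/RCP monthly percentage changes. The deltas
# are applied to the *cycled observed series* (1986, 1987, ... 2005,
# repeat), not to a flat climatological mean: scaling a mean destroys
# interannual variability and with it every drought, while cycling the
# observed years preserves the variance structure the percentile index
# needs. Exposure is then recomputed over the combined historical plus
# projected series so the rolling 30-year percentile baseline moves
# forward into the scenario era ("droughts in living memory").

#' Apply rainfall percentage-change deltas to a historical series
#'
#' For each projection year y and month m the scenario rainfall is
#' `hist_rain(cycle_year(y), m) * (1 + pct_change(y, m) / 100)`, where
#' `cycle_year` cycles deterministically through the baseline years in
#' fixed order starting at the projection start year. Months before the
#' first delta year pass through unchanged.
#'
#' @param hist historical rainfall panel (`region_id`, `year`, `month`,
#'   `rain_mm`) covering the baseline range.
#' @param deltas delta table (`gcm`, `rcp`, `region_id`, `year`,
#'   `month`, `pct_change`); one scenario (single gcm x rcp) per call.
#' @param baseline `c(first, last)` baseline climate years, default
#'   1986-2005.
#' @return scenario series: `gcm`, `rcp`, `region_id`, `year`, `month`,
#'   `rain_mm`, continuous from the start of `hist` to the last delta
#'   year.
#' @export
apply_deltas <- function(hist, deltas, baseline = c(1986, 2005)) {
  stopifnot(all(c("region_id", "year", "month", "rain_mm") %in% names(hist)),
            all(c("gcm", "rcp", "region_id", "year", "month", "pct_change")
                %in% names(deltas)))
  if (nrow(unique(deltas[, c("gcm", "rcp")])) != 1L) {
    stop("apply_deltas handles one gcm x rcp per call", call. = FALSE)
  }
  if (any(deltas$pct_change <= -100)) {
    stop("pct_change must be > -100", call. = FALSE)
  }
  base_years <- baseline[1]:baseline[2]
  if (!all(base_years %in% hist$year)) {
    stop("historical series does not cover the baseline years", call. = FALSE)
  }
  start <- min(deltas$year)
  end <- max(deltas$year)
  parts <- lapply(split(hist, hist$region_id), function(h) {
    rid <- h$region_id[1]
    d <- deltas[deltas$region_id == rid, , drop = FALSE]
    if (nrow(d) != 12L * (end - start + 1L)) {
      stop("missing delta rows for region ", rid, call. = FALSE)
    }
    h <- h[order(month_index(h$year, h$month)), , drop = FALSE]
    pre <- h[h$year < start, c("region_id", "year", "month", "rain_mm")]
    cyc_year <- baseline[1] + (d$year - start) %% length(base_years)
    base_idx <- match(month_index(cyc_year, d$month),
                      month_index(h$year, h$month))
    if (anyNA(base_idx)) stop("baseline month missing in history", call. = FALSE)
    proj <- data.frame(region_id = rid, year = d$year, month = d$month,
                       rain_mm = h$rain_mm[base_idx] * (1 + d$pct_change / 100),
                       stringsAsFactors = FALSE)
    proj <- proj[order(month_index(proj$year, proj$month)), , drop = FALSE]
    rbind(pre, proj)
  })
  out <- do.call(rbind, parts)
  out$gcm <- deltas$gcm[1]
  out$rcp <- deltas$rcp[1]
  rownames(out) <- NULL
  out[, c("gcm", "rcp", "region_id", "year", "month", "rain_mm")]
}

#' Drought exposure under a scenario
#'
#' Runs the drought index over the combined historical + projected
#' rainfall so percentiles are benchmarked against the rolling 30-year
#' look-back that rolls into the scenario era.
#'
#' @param series scenario series from [apply_deltas()] (or any
#'   continuous rainfall panel; `gcm`/`rcp` columns are carried along
#'   if present).
#' @param lookback_years look-back window, default 30.
#' @return exposure series with `gcm`/`rcp` attached when available.
#' @export
scenario_exposure <- function(series, lookback_years = 30) {
  rain <- series[, c("region_id", "year", "month", "rain_mm")]
  ex <- drought_counter(score_series(rain, lookback_years = lookback_years))
  if (all(c("gcm", "rcp") %in% names(series))) {
    ex$gcm <- series$gcm[1]
    ex$rcp <- series$rcp[1]
  }
  ex
}

#' Mean full-drought durations by region, scenario and period
#'
#' Tabulates, for each scenario exposure series and analysis period,
#' the mean reported spell duration (full-drought months) per region
#' together with spell counts, the numeric content of a
#' drought-duration comparison figure.
#'
#' @param exposures named list of exposure series (names are scenario
#'   labels, e.g. `"historical"`, `"GFDL-ESM2M.RCP4.5"`).
#' @param periods named list of `c(first_year, last_year)` periods;
#'   each scenario is summarized over each period it covers.
#' @return data frame `scenario`, `period`, `region_id`, `n_spells`,
#'   `mean_duration`, `max_duration`.
#' @export
duration_summary_by_scenario <- function(exposures, periods) {
  stopifnot(length(exposures) > 0, !is.null(names(exposures)))
  rows <- list()
  for (sc in names(exposures)) {
    ex <- exposures[[sc]]
    if (nrow(ex) == 0L) stop("empty exposure for ", sc, call. = FALSE)
    for (pd in names(periods)) {
      p <- periods[[pd]]
      if (min(ex$year) > p[1] || max(ex$year) < p[2]) next
      sm <- summarize_droughts(ex, period = p)$summary
      if (nrow(sm) == 0L) {
        sm <- data.frame(region_id = unique(ex$region_id), n_spells = 0L,
                         mean_duration = NA_real_, max_duration = NA_real_,
                         stringsAsFactors = FALSE)
      }
      sm$scenario <- sc
      sm$period <- pd
      rows[[length(rows) + 1L]] <- sm
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("scenario", "period", "region_id", "n_spells",
          "mean_duration", "max_duration")]
}
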