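# Drought-attributable suicide numbers.
#
# For each stratum the attributable number over a period is
#   AN = sum over full-drought region-months of
#        (1 - exp(-beta * X)) * HistoricalNumber(region, calendar month)
# expressed per annum by dividing by the calendar years in the period
# (including years with no drought months). Only months in full drought
# (counter >= 7, i.e. drought index > 6) contribute. Uncertainty comes
# from Monte Carlo draws of beta around its estimate.

#' Historical mean deaths by calendar month
#'
#' Average monthly deaths per region x age x sex x calendar month over
#' the historical period's years.
#'
#' @param panel suicide panel (`region_id`, `year`, `month`,
#'   `age_group`, `sex`, `count`).
#' @param period `c(first_year, last_year)`, default 1971-1999.
#' @return data frame `region_id`, `month`, `age_group`, `sex`,
#'   `mean_deaths`.
#' @export
historical_monthly_means <- function(panel, period = c(1971, 1999)) {
  keep <- panel$year >= period[1] & panel$year <= period[2]
  if (!any(keep)) stop("empty period", call. = FALSE)
  d <- panel[keep, , drop = FALSE]
  agg <- stats::aggregate(count ~ region_id + month + age_group + sex,
                          data = d, FUN = mean)
  names(agg)[names(agg) == "count"] <- "mean_deaths"
  agg[order(agg$region_id, agg$age_group, agg$sex, agg$month), ,
      drop = FALSE]
}

# Internal: weights (historical means) and exposures of the
# full-drought months of one stratum over a period.
full_drought_terms <- function(exposure, hist, period) {
  if (min(exposure$year) > period[1] || max(exposure$year) < period[2]) {
    stop("period outside exposure coverage", call. = FALSE)
  }
  ex <- exposure[exposure$year >= period[1] & exposure$year <= period[2] &
                 exposure$counter >= 7L, , drop = FALSE]
  if (nrow(ex) == 0L) {
    return(list(X = numeric(0), w = numeric(0),
                years = period[2] - period[1] + 1))
  }
  m <- merge(ex[, c("region_id", "year", "month", "X")],
             hist[, c("region_id", "month", "mean_deaths")],
             by = c("region_id", "month"))
  list(X = m$X, w = m$mean_deaths, years = period[2] - period[1] + 1)
}

#' Attributable number per annum for one stratum
#'
#' @param beta drought slope for the stratum (log rate ratio per unit
#'   `X = log(1 + counter)`); may be negative (protective).
#' @param exposure exposure series covering `period`.
#' @param hist historical monthly means for this stratum only
#'   (`region_id`, `month`, `mean_deaths`; subset the result of
#'   [historical_monthly_means()]).
#' @param period `c(first_year, last_year)` accounting window.
#' @return scalar AN per annum (0 when `beta = 0` or no full-drought
#'   months; negative when `beta < 0`).
#' @export
attributable_number <- function(beta, exposure, hist, period) {
  tr <- full_drought_terms(exposure, hist, period)
  if (length(tr$X) == 0L) return(0)
  sum((1 - exp(-beta * tr$X)) * tr$w) / tr$years
}

#' Monte Carlo confidence interval for an attributable number
#'
#' Draws `n` slopes from `Normal(beta_hat, se)` independently for the
#' stratum, recomputes the AN for each draw, and reports the empirical
#' 2.5th and 97.5th percentiles. The point estimate uses `beta_hat`
#' itself; the draw median is also reported.
#'
#' @param fit a `drought_fit`, or a list with elements `beta` and `se`.
#' @param exposure,hist,period as in [attributable_number()].
#' @param age_group,sex,is_urban stratum selectors when `fit` is a
#'   `drought_fit`.
#' @param n number of Monte Carlo iterations, default 1000.
#' @param seed integer seed; fixed seed gives bit-identical CIs.
#' @return list of class `attribution_result`: `an`, `ci_low`,
#'   `ci_high`, `mc_median`, `draws` (AN per draw, for paired
#'   comparisons), `beta`, `se`, `n_mc`, `seed`, `period`.
#' @export
monte_carlo_ci <- function(fit, exposure, hist, period,
                           age_group = NULL, sex = NULL, is_urban = FALSE,
                           n = 1000, seed = 1L) {
  if (inherits(fit, "drought_fit")) {
    sl <- drought_slope(fit, age_group, sex, is_urban)
  } else {
    sl <- fit
  }
  if (!is.numeric(sl$se) || sl$se < 0) stop("invalid SE", call. = FALSE)
  if (sl$se == 0) {
    an <- attributable_number(sl$beta, exposure, hist, period)
    return(structure(list(an = an, ci_low = an, ci_high = an,
                          mc_median = an, draws = rep(an, n),
                          beta = sl$beta, se = 0, n_mc = n, seed = seed,
                          period = period),
                     class = "attribution_result"))
  }
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  tr <- full_drought_terms(exposure, hist, period)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bstar <- stats::rnorm(n, sl$beta, sl$se)
  if (length(tr$X) == 0L) {
    draws <- rep(0, n)
    an <- 0
  } else {
    # n x n_months matrix of attributable fractions
    af <- 1 - exp(-outer(bstar, tr$X))
    draws <- as.numeric(af %*% tr$w) / tr$years
    an <- sum((1 - exp(-sl$beta * tr$X)) * tr$w) / tr$years
  }
  q <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(list(an = an, ci_low = q[1], ci_high = q[2],
                 mc_median = stats::median(draws), draws = draws,
                 beta = sl$beta, se = sl$se, n_mc = n, seed = seed,
                 period = period),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("AN per annum %.3f (95%% CI %.3f, %.3f), n_mc = %d\n",
              x$an, x$ci_low, x$ci_high, x$n_mc))
  invisible(x)
}

#' Percentage change between two attributable numbers
#'
#' `100 * (scenario - historical) / historical`; errors when the
#' historical AN is zero.
#'
#' @param an_hist,an_scen scalar ANs.
#' @return percentage change.
#' @export
an_percent_change <- function(an_hist, an_scen) {
  if (an_hist == 0) stop("historical AN is zero", call. = FALSE)
  100 * (an_scen - an_hist) / an_hist
}

#' Compare attribution results across scenarios and sexes
#'
#' Builds the scenario comparison table: percentage change of each
#' scenario AN against the historical AN per stratum, and the
#' male-minus-female AN difference per scenario for each age group.
#' When results carry paired Monte Carlo draws (same seed structure,
#' same draw index pairing), empirical 95% CIs are attached; with
#' point-only inputs the CI columns are `NA`.
#'
#' @param results data frame or list-of-lists with one entry per
#'   (age_group, sex, scenario): fields `age_group`, `sex`, `scenario`,
#'   `an`, optional `draws`. Use `scenario = "historical"` for the
#'   baseline entries.
#' @return list with `pct_change` (age_group, sex, scenario, pct,
#'   ci_low, ci_high) and `sex_difference` (age_group, scenario, diff,
#'   ci_low, ci_high).
#' @export
compare_scenarios <- function(results) {
  if (is.data.frame(results)) {
    results <- lapply(seq_len(nrow(results)), function(i) as.list(results[i, ]))
  }
  key <- function(r) paste(r$age_group, r$sex, r$scenario, sep = "|")
  names(results) <- vapply(results, key, character(1))
  scens <- unique(vapply(results, function(r) r$scenario, character(1)))
  ages <- unique(vapply(results, function(r) r$age_group, character(1)))
  pct <- list()
  for (r in results) {
    if (r$scenario == "historical") next
    h <- results[[paste(r$age_group, r$sex, "historical", sep = "|")]]
    if (is.null(h)) next
    row <- data.frame(age_group = r$age_group, sex = r$sex,
                      scenario = r$scenario,
                      pct = an_percent_change(h$an, r$an),
                      ci_low = NA_real_, ci_high = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(r$draws) && !is.null(h$draws) &&
        length(r$draws) == length(h$draws)) {
      ok <- h$draws != 0
      pc <- 100 * (r$draws[ok] - h$draws[ok]) / h$draws[ok]
      q <- unname(stats::quantile(pc, c(0.025, 0.975)))
      row$ci_low <- q[1]
      row$ci_high <- q[2]
    }
    pct[[length(pct) + 1L]] <- row
  }
  sd_rows <- list()
  for (sc in scens) {
    for (ag in ages) {
      m <- results[[paste(ag, "male", sc, sep = "|")]]
      f <- results[[paste(ag, "female", sc, sep = "|")]]
      if (is.null(m) || is.null(f)) next
      row <- data.frame(age_group = ag, scenario = sc, diff = m$an - f$an,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE)
      if (!is.null(m$draws) && !is.null(f$draws) &&
          length(m$draws) == length(f$draws)) {
        dd <- m$draws - f$draws
        q <- unname(stats::quantile(dd, c(0.025, 0.975)))
        row$ci_low <- q[1]
        row$ci_high <- q[2]
      }
      sd_rows[[length(sd_rows) + 1L]] <- row
    }
  }
  list(
    pct_change = if (length(pct)) do.call(rbind, pct) else NULL,
    sex_difference = if (length(sd_rows)) do.call(rbind, sd_rows) else NULL
  )
}
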