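# Modified Hutchinson Drought Severity Index.
#
# The index expresses the rolling six-month rainfall total ending in a
# nominated month as a percentile relative to totals ending in the same
# calendar month over a rolling 30-year look-back window (the nominated
# year plus the previous 29), then rescales percentiles linearly so that
# the 1st, 50th and 99th percentiles map to scores of -4, 0 and +4.
# A month with score <= -1 is in mild drought; the seventh consecutive
# mild-drought month opens a full drought, which ends when the score
# rises above -1.

# Slope of the anchor-constrained linear map: (99 - 50) / 4 = 12.25
# percentile points per index unit, so score = (p - 50) / 12.25 hits
# 1 -> -4, 50 -> 0 and 99 -> +4 exactly.
HDSI_SCALE <- 12.25

#' Rolling six-month rainfall totals
#'
#' For each region-month, the sum of rainfall over the six months up to
#' and including that month. The first five months of each region's
#' series have no defined total and are returned as `NA`.
#'
#' @param rain data frame with columns `region_id`, `year`, `month`,
#'   `rain_mm`; contiguous months within each region.
#' @return the input with an added `total` column (mm over 6 months).
#' @export
#' @examples
#' rain <- data.frame(region_id = "A", year = 2000, month = 1:12, rain_mm = 50)
#' six_month_totals(rain)$total
six_month_totals <- function(rain) {
  stopifnot(all(c("region_id", "year", "month", "rain_mm") %in% names(rain)))
  if (any(rain$rain_mm < 0)) stop("rain_mm must be non-negative", call. = FALSE)
  check_contiguous(rain)
  rain <- rain[order(rain$region_id, month_index(rain$year, rain$month)), ,
               drop = FALSE]
  parts <- lapply(split(rain, rain$region_id), function(d) {
    if (nrow(d) < 6L) stop("need at least 6 months per region", call. = FALSE)
    # windowed sum in a fixed order (not cumsum differencing) so that
    # identical six-month windows give bitwise-identical totals; the
    # delta-change replay of baseline years relies on exact ties
    tot <- rep(NA_real_, nrow(d))
    tot[6:nrow(d)] <- rowSums(stats::embed(d$rain_mm, 6))
    d$total <- tot
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Hutchinson score of one six-month total against a look-back set
#'
#' Computes the Hazen mid-rank percentile of `total` within
#' `lookback_totals` (which must include the nominated total itself) and
#' maps it to an index score by the anchor-constrained linear rescaling
#' `(p - 50) / 12.25`, clamped to `[-4, 4]`. Ties take the mid-rank, so
#' a fully tied (constant-rainfall) look-back set scores exactly 0.
#'
#' @param total six-month rainfall total for the nominated month.
#' @param lookback_totals totals for the same calendar month over the
#'   look-back window, including the nominated value.
#' @return scalar score in `[-4, 4]`.
#' @export
hutchinson_score <- function(total, lookback_totals) {
  if (length(lookback_totals) == 0L) {
    stop("empty look-back set", call. = FALSE)
  }
  if (anyNA(total) || anyNA(lookback_totals)) {
    stop("missing totals in look-back set", call. = FALSE)
  }
  n <- length(lookback_totals)
  r <- sum(lookback_totals < total) + (sum(lookback_totals == total) + 1) / 2
  p <- 100 * (r - 0.5) / n
  clamp((p - 50) / HDSI_SCALE, -4, 4)
}

#' Hutchinson score series with a rolling look-back window
#'
#' Scores every month whose calendar month has a complete set of
#' six-month totals over the look-back window (the nominated year and
#' the previous `lookback_years - 1` years). With input starting in
#' January of year y0 the first scorable month is June of
#' `y0 + lookback_years - 1` (earlier calendar months lack the total for
#' the first window year).
#'
#' @param rain rainfall panel (`region_id`, `year`, `month`, `rain_mm`).
#' @param lookback_years window length in years, default 30.
#' @return data frame `region_id`, `year`, `month`, `total`, `score`.
#' @export
score_series <- function(rain, lookback_years = 30) {
  stopifnot(lookback_years >= 1)
  tot <- six_month_totals(rain)
  parts <- lapply(split(tot, tot$region_id), function(d) {
    d <- d[order(month_index(d$year, d$month)), , drop = FALSE]
    d$score <- NA_real_
    for (m in 1:12) {
      sel <- which(d$month == m)
      if (length(sel) < lookback_years) next
      yrs <- d$year[sel]
      vals <- d$total[sel]
      # windows of `lookback_years` consecutive totals ending at each year
      if (length(vals) >= lookback_years) {
        win <- stats::embed(vals, lookback_years) # row i: vals[i+L-1] .. vals[i]
        nom <- win[, 1L]
        ok <- stats::complete.cases(win)
        less <- rowSums(win < nom)
        eq <- rowSums(win == nom)
        r <- less + (eq + 1) / 2
        p <- 100 * (r - 0.5) / lookback_years
        sc <- clamp((p - 50) / HDSI_SCALE, -4, 4)
        tgt <- sel[seq(lookback_years, length(sel))]
        d$score[tgt[ok]] <- sc[ok]
      }
    }
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- out[!is.na(out$score), c("region_id", "year", "month", "total", "score")]
  if (nrow(out) == 0L) stop("insufficient history for look-back window", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Drought accounting: mild-drought counter, full-drought flag, exposure
#'
#' Applies the drought state machine to a score series: the counter
#' increments while the score is at or below -1 (mild drought, threshold
#' inclusive) and resets to zero the month the score rises above -1.
#' Full drought is declared from the seventh consecutive mild-drought
#' month. The regression exposure is `X = log(1 + counter)`.
#'
#' @param scores data frame with `region_id`, `year`, `month`, `score`
#'   (contiguous months per region), e.g. from [score_series()].
#' @return exposure series: input plus `counter`, `full_drought`, `X`.
#' @export
drought_counter <- function(scores) {
  stopifnot(all(c("region_id", "year", "month", "score") %in% names(scores)))
  check_contiguous(scores)
  scores <- scores[order(scores$region_id,
                         month_index(scores$year, scores$month)), , drop = FALSE]
  parts <- lapply(split(scores, scores$region_id), function(d) {
    dry <- as.integer(d$score <= -1)
    cs <- cumsum(dry)
    # counter = run length of current dry streak (0 outside drought)
    d$counter <- as.integer(cs - cummax((1L - dry) * cs))
    d$full_drought <- d$counter >= 7L
    d$X <- log1p(d$counter)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Tabulate drought spells and summarize durations
#'
#' A spell is a maximal run of consecutive mild-drought months whose
#' counter reaches at least 7 (i.e. the run becomes a full drought).
#' `n_full_months = n_mild_months - 6` is the reported duration; runs
#' shorter than 7 months are within normal variability and are ignored.
#'
#' @param exposure exposure series from [drought_counter()].
#' @param period optional `c(first_year, last_year)`; spells are
#'   assigned to the period by their start month.
#' @return list with `spells` (one row per spell: `region_id`,
#'   `start_year`, `start_month`, `n_mild_months`, `n_full_months`,
#'   `duration_reported`) and `summary` (per region: `n_spells`,
#'   `mean_duration`, `max_duration`).
#' @export
summarize_droughts <- function(exposure, period = NULL) {
  stopifnot(all(c("region_id", "year", "month", "counter") %in% names(exposure)))
  if (!is.null(period)) {
    keep <- exposure$year >= period[1] & exposure$year <= period[2]
    if (!any(keep)) stop("empty period", call. = FALSE)
  }
  rows <- list()
  for (d in split(exposure, exposure$region_id)) {
    d <- d[order(month_index(d$year, d$month)), , drop = FALSE]
    dry <- d$counter > 0L
    if (!any(dry)) next
    r <- rle(dry)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 7L)) {
      s <- starts[k]
      if (!is.null(period) &&
          (d$year[s] < period[1] || d$year[s] > period[2])) next
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = d$region_id[s],
        start_year = d$year[s], start_month = d$month[s],
        n_mild_months = r$lengths[k],
        n_full_months = r$lengths[k] - 6L,
        duration_reported = r$lengths[k] - 6L,
        stringsAsFactors = FALSE
      )
    }
  }
  spells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(), start_year = integer(),
               start_month = integer(), n_mild_months = integer(),
               n_full_months = integer(), duration_reported = integer(),
               stringsAsFactors = FALSE)
  if (nrow(spells)) {
    agg <- do.call(rbind, lapply(split(spells, spells$region_id), function(s) {
      data.frame(region_id = s$region_id[1], n_spells = nrow(s),
                 mean_duration = mean(s$duration_reported),
                 max_duration = max(s$duration_reported),
                 stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(region_id = character(), n_spells = integer(),
                      mean_duration = numeric(), max_duration = numeric(),
                      stringsAsFactors = FALSE)
  }
  list(spells = spells, summary = agg)
}

#' Interquartile range of the log drought exposure
#'
#' The IQR of `X = log(1 + counter)` over a configurable set of months;
#' used as the reporting unit for relative risks. Recomputed from the
#' data at hand, never hard-coded.
#'
#' @param exposure exposure series from [drought_counter()].
#' @param months which months enter: `"all"`, `"mild"` (counter > 0) or
#'   `"full"` (counter >= 7).
#' @return scalar IQR (type-7 quantiles).
#' @export
exposure_iqr <- function(exposure, months = c("all", "mild", "full")) {
  months <- match.arg(months)
  x <- switch(months,
    all = exposure$X,
    mild = exposure$X[exposure$counter > 0L],
    full = exposure$X[exposure$counter >= 7L]
  )
  if (length(x) == 0L) stop("no months selected for IQR", call. = FALSE)
  unname(diff(stats::quantile(x, c(0.25, 0.75))))
}
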