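# Poisson time-series exposure-response model.
#
# Monthly suicide counts are regressed on log drought duration with one
# linear slope per age x sex x rural/urban stratum, a natural cubic
# spline trend (df = 3) interacted with age x sex, a cyclic cubic
# seasonal spline (df = 4), region fixed effects, the temperature
# anomaly, and a log-population offset. Spline degrees of freedom are
# fixed at the reported final-model values; a sensitivity refit at
# other df is available through the same interface.

#' Natural cubic spline basis
#'
#' `df` columns, linear beyond the boundary knots, interior knots at
#' equally spaced quantiles of `t` (the [splines::ns()] parameterization
#' without an intercept column).
#'
#' @param t numeric sequence (e.g. month index).
#' @param df degrees of freedom, default 3.
#' @return matrix with `df` columns and attributes for re-evaluation.
#' @export
natural_cubic_basis <- function(t, df = 3) {
  stopifnot(df >= 1)
  if (df >= length(unique(t))) {
    stop("df exceeds number of distinct t values", call. = FALSE)
  }
  splines::ns(t, df = df)
}

#' Cyclic cubic spline basis for calendar month
#'
#' Periodic cubic B-spline basis on the month circle (period 12): the
#' fitted seasonal curve and its first two derivatives are continuous
#' across the December-January wrap. Evaluation wraps any real-valued
#' month into [0, 12), so month 12 + eps and month eps coincide.
#'
#' @param month numeric vector (calendar months, 1-12, fractional
#'   allowed).
#' @param df number of basis columns, default 4. The columns span
#'   constants (they sum to 1 at every point), so one column is
#'   redundant with an intercept; [fit_poisson()] handles that by
#'   dropping a column internally.
#' @return matrix with `df` columns.
#' @export
cyclic_cubic_basis <- function(month, df = 4) {
  stopifnot(df >= 2, df <= 12)
  knots <- seq(0, 12, length.out = df + 1)
  x <- month %% 12
  mgcv::cSplineDes(x, knots)
}

# Identifiable seasonal design block: cyclic basis with df + 1 columns,
# centered over the 12 calendar months and one redundant column dropped
# (the raw columns sum to 1 and would alias the intercept). Shared by
# the model fitter and the count generator so the generative seasonal
# curve lies exactly in the fitted span.
season_basis_cc <- function(month, df) {
  B <- cyclic_cubic_basis(month, df = df + 1)
  B <- sweep(B, 2, colMeans(cyclic_cubic_basis(1:12, df = df + 1)))
  B[, -1, drop = FALSE]
}

# Stratum labels in fixed order for the 12 drought-slope columns.
drought_slope_names <- function() {
  g <- expand.grid(age_group = AGE_GROUPS, sex = SEXES,
                   is_urban = c(FALSE, TRUE), stringsAsFactors = FALSE)
  paste0("drought.", stratum_key(g$age_group, g$sex, g$is_urban))
}

# Assemble the model frame: merge panels, restrict to the fit period.
assemble_model_data <- function(panel, exposure, temps, period) {
  need <- c("region_id", "year", "month", "age_group", "sex", "count", "pop")
  stopifnot(all(need %in% names(panel)))
  if (any(panel$pop <= 0)) stop("non-positive population", call. = FALSE)
  dat <- merge(panel[, need],
               exposure[, c("region_id", "year", "month", "X")],
               by = c("region_id", "year", "month"))
  dat <- merge(dat, temps[, c("region_id", "year", "month", "tmax_anomaly_c")],
               by = c("region_id", "year", "month"))
  lo <- month_index(period[1], period[2])
  hi <- month_index(period[3], period[4])
  dat <- dat[month_index(dat$year, dat$month) >= lo &
             month_index(dat$year, dat$month) <= hi, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no rows in fit period", call. = FALSE)
  dat[order(dat$region_id, dat$age_group, dat$sex,
            month_index(dat$year, dat$month)), , drop = FALSE]
}

# Build the design matrix. Drought slopes are 12 separate columns (no
# reference drop) so each stratum coefficient is directly readable.
build_design <- function(dat, urban_map, time_df = 3, month_df = 4,
                         seasonal = c("cc", "sincos")) {
  seasonal <- match.arg(seasonal)
  dat$age_group <- factor(dat$age_group, levels = AGE_GROUPS)
  dat$sex <- factor(dat$sex, levels = SEXES)
  dat$region_id <- factor(dat$region_id)
  tind <- month_index(dat$year, dat$month)
  Bt <- natural_cubic_basis(tind, df = time_df)
  if (seasonal == "cc") {
    Bm <- season_basis_cc(dat$month, df = month_df)
  } else {
    Bm <- cbind(sin(2 * pi * dat$month / 12), cos(2 * pi * dat$month / 12))
  }
  colnames(Bm) <- paste0("season", seq_len(ncol(Bm)))
  mf <- data.frame(dat, Bt = I(Bt), Bm = I(Bm))
  mm <- stats::model.matrix(
    ~ region_id + age_group * sex * Bt + Bm + tmax_anomaly_c, data = mf
  )
  dk <- stratum_key(as.character(dat$age_group), as.character(dat$sex),
                    urban_map[as.character(dat$region_id)])
  slopes <- drought_slope_names()
  D <- matrix(0, nrow(dat), length(slopes), dimnames = list(NULL, slopes))
  D[cbind(seq_len(nrow(dat)), match(paste0("drought.", dk), slopes))] <- dat$X
  cbind(mm, D)
}

#' Fit the Poisson exposure-response model
#'
#' Maximum-likelihood Poisson regression with log link and
#' log-population offset, estimated by iteratively reweighted least
#' squares (convergence when the relative deviance change drops below
#' `1e-8`). Drought slopes are parameterized as 12 separate
#' stratum-specific columns; reference levels for region, age and sex
#' are dropped.
#'
#' @param panel suicide panel: `region_id`, `year`, `month`,
#'   `age_group`, `sex`, `count`, `pop` (complete stratum grid, zeros
#'   explicit).
#' @param exposure exposure series from [drought_counter()].
#' @param temps temperature anomaly panel.
#' @param urban_map named logical vector: is each region urban?
#' @param period fit period `c(year, month, year, month)`; default
#'   January 1970 through October 2007.
#' @param time_df,month_df spline degrees of freedom (defaults 3, 4).
#' @param seasonal `"cc"` for the cyclic cubic spline, `"sincos"` for
#'   the sine/cosine sensitivity variant.
#' @return object of class `drought_fit`: `coefficients`, `se`, `vcov`,
#'   `deviance`, `df_residual`, `pearson` residual sum of squares,
#'   `fitted`, `y`, `converged`, plus the design metadata.
#' @export
fit_poisson <- function(panel, exposure, temps, urban_map,
                        period = c(1970, 1, 2007, 10),
                        time_df = 3, month_df = 4,
                        seasonal = c("cc", "sincos")) {
  seasonal <- match.arg(seasonal)
  dat <- assemble_model_data(panel, exposure, temps, period)
  X <- build_design(dat, urban_map, time_df, month_df, seasonal)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient (", qrX$rank, " < ", ncol(X), ")",
         call. = FALSE)
  }
  off <- log(dat$pop)
  # start at the crude overall rate to keep early IRLS steps tame
  start <- numeric(ncol(X))
  start[1] <- log(sum(dat$count) / sum(dat$pop))
  fit <- stats::glm.fit(X, dat$count, family = stats::poisson(),
                        offset = off, start = start,
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 100))
  if (!fit$converged) stop("IRLS did not converge", call. = FALSE)
  w <- fit$weights # mu at convergence
  XtWX <- crossprod(X * sqrt(w))
  vcov <- chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  mu <- fit$fitted.values
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    se = stats::setNames(sqrt(diag(vcov)), colnames(X)),
    vcov = vcov,
    deviance = fit$deviance,
    df_residual = fit$df.residual,
    pearson = sum((dat$count - mu)^2 / mu),
    fitted = mu, y = dat$count,
    converged = fit$converged,
    n = nrow(dat), period = period,
    time_df = time_df, month_df = month_df, seasonal = seasonal
  ), class = "drought_fit")
}

#' @export
print.drought_fit <- function(x, ...) {
  cat("Poisson exposure-response fit:", x$n, "rows,",
      length(x$coefficients), "coefficients\n")
  cat("deviance", format(x$deviance, digits = 6),
      "on", x$df_residual, "df; dispersion",
      format(x$pearson / x$df_residual, digits = 3), "\n")
  sl <- grep("^drought\\.", names(x$coefficients))
  tab <- data.frame(beta = x$coefficients[sl], se = x$se[sl])
  print(round(tab, 4))
  invisible(x)
}

#' Extract a stratum drought slope and its standard error
#'
#' @param fit a `drought_fit`.
#' @param age_group,sex,is_urban stratum identifiers.
#' @return list `beta`, `se`.
#' @export
drought_slope <- function(fit, age_group, sex, is_urban = FALSE) {
  nm <- paste0("drought.", stratum_key(age_group, sex, is_urban))
  if (!nm %in% names(fit$coefficients)) {
    stop("unknown stratum: ", nm, call. = FALSE)
  }
  list(beta = unname(fit$coefficients[nm]), se = unname(fit$se[nm]))
}

#' Relative risk per IQR increase in log drought exposure
#'
#' `RR = exp(beta * iqr)` with a Wald 95% interval
#' `exp((beta +/- 1.96 se) * iqr)`. The IQR must be supplied explicitly
#' (see [exposure_iqr()]); which months it was computed over is the
#' caller's reporting choice.
#'
#' @param fit a `drought_fit`, or a single numeric slope (then `se`
#'   may be given directly).
#' @param iqr positive IQR of the log drought exposure.
#' @param age_group,sex,is_urban stratum identifiers (ignored when
#'   `fit` is numeric).
#' @param se optional standard error when `fit` is numeric.
#' @return list `rr`, `lo`, `hi`, `beta`, `iqr`.
#' @export
rr_per_iqr <- function(fit, iqr, age_group = NULL, sex = NULL,
                       is_urban = FALSE, se = NULL) {
  stopifnot(is.numeric(iqr), iqr > 0)
  if (is.numeric(fit)) {
    beta <- fit
  } else {
    sl <- drought_slope(fit, age_group, sex, is_urban)
    beta <- sl$beta
    se <- sl$se
  }
  out <- list(rr = exp(beta * iqr), beta = beta, iqr = iqr)
  if (!is.null(se)) {
    out$lo <- exp((beta - 1.96 * se) * iqr)
    out$hi <- exp((beta + 1.96 * se) * iqr)
  }
  out
}

#' Pearson dispersion statistic
#'
#' Pearson chi-squared divided by residual degrees of freedom; values
#' near 1 indicate the Poisson variance assumption is adequate.
#'
#' @param fit a `drought_fit`.
#' @return scalar dispersion.
#' @export
dispersion <- function(fit) {
  if (fit$df_residual <= 0) {
    stop("zero residual degrees of freedom", call. = FALSE)
  }
  fit$pearson / fit$df_residual
}
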