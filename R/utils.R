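# Shared helpers: calendar arithmetic, seeded RNG derivation, validation.

AGE_GROUPS <- c("10-29", "30-49", "50+")
SEXES <- c("male", "female")

#' Month index on a continuous scale
#'
#' Maps (year, month) to a single integer so that consecutive calendar
#' months differ by exactly 1. Used throughout for gap detection and
#' ordering.
#'
#' @param year,month integer vectors (month in 1..12)
#' @return integer vector
#' @keywords internal
month_index <- function(year, month) {
  as.integer(year) * 12L + as.integer(month) - 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from one master seed; each named
#' stage (rainfall, temperature, suicides, ...) gets its own derived
#' stream so re-running a single stage reproduces bit-identically.
#' The derivation is a small polynomial string hash folded into the
#' 32-bit signed integer range.
#'
#' @param master integer master seed
#' @param stage character stage name
#' @return integer seed in [0, 2^31 - 2]
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(master)) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Expand a contiguous monthly grid between two (year, month) endpoints.
ym_grid <- function(start, end) {
  s <- month_index(start[1], start[2])
  e <- month_index(end[1], end[2])
  if (s > e) stop("start must precede end", call. = FALSE)
  idx <- s:e
  data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
}

# Check a panel has one row per contiguous month within each region.
check_contiguous <- function(df, by = "region_id") {
  sp <- split(df, df[[by]])
  for (nm in names(sp)) {
    mi <- sort(month_index(sp[[nm]]$year, sp[[nm]]$month))
    if (anyDuplicated(mi)) {
      stop("duplicate months for ", by, " ", nm, call. = FALSE)
    }
    if (length(mi) > 1L && any(diff(mi) != 1L)) {
      stop("gap in monthly series for ", by, " ", nm, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Stratum key used for drought-slope columns: age x sex x rural/urban.
stratum_key <- function(age_group, sex, is_urban) {
  paste0(age_group, ".", sex, ".", ifelse(is_urban, "urban", "rural"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
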