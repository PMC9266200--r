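# Drought index: rolling totals, percentile scoring, state machine.

test_that("six-month totals match direct summation", {
  rain <- scripted_rainfall(c(10, 20, 30, 40, 50, 60))
  tot <- six_month_totals(rain)
  expect_true(all(is.na(tot$total[1:5])))
  expect_equal(tot$total[6], 210)

  const <- scripted_rainfall(rep(50, 24))
  expect_equal(six_month_totals(const)$total[6:24], rep(300, 19))

  # brute-force oracle on a random series; one zeroed month must drop
  # exactly 6 consecutive totals by 50
  set.seed(42)
  x <- rgamma(60, 2, scale = 25)
  tot1 <- six_month_totals(scripted_rainfall(x))$total
  brute <- vapply(6:60, function(t) sum(x[(t - 5):t]), numeric(1))
  expect_equal(tot1[6:60], brute)

  y <- rep(50, 60)
  y[30] <- 0
  tot2 <- six_month_totals(scripted_rainfall(y))$total
  drop <- which(abs(tot2 - 300) > 1e-12)
  expect_equal(drop, 30:35)
  expect_equal(tot2[30:35], rep(250, 6))
})

test_that("six_month_totals rejects gaps and short series", {
  rain <- scripted_rainfall(rep(50, 12))
  expect_error(six_month_totals(rain[-4, ]), "gap")
  expect_error(six_month_totals(scripted_rainfall(rep(50, 5))),
               "at least 6 months")
})

test_that("hutchinson_score reproduces the percentile anchors", {
  # median of an odd tie-free set -> score 0
  lb <- c(10, 20, 30, 40, 50)
  expect_equal(hutchinson_score(30, lb), 0)
  # strictly below every value, n = 360 -> clamped to -4
  lb360 <- seq(100, by = 1, length.out = 360)
  expect_equal(hutchinson_score(100, lb360), -4)
  # total ties (constant rainfall) -> mid-rank p = 50 -> 0
  expect_equal(hutchinson_score(300, rep(300, 30)), 0)
  # exact 25th percentile: rank 13 of 50 gives p = 25
  lb50 <- sort(runif(50)) * 100
  expect_equal(hutchinson_score(lb50[13], lb50), (25 - 50) / 12.25)
  expect_error(hutchinson_score(1, numeric(0)), "empty")
})

test_that("score is monotone in the nominated total", {
  set.seed(7)
  lb <- rgamma(30, 2, scale = 100)
  vals <- sort(c(lb, lb + 0.5))
  scores <- vapply(vals, function(v) hutchinson_score(v, c(lb, v)),
                   numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("score_series starts at the first complete look-back window", {
  cfg <- sim_config(regions = tiny_regions()[1], start = c(1940, 1),
                    end = c(2007, 12), seed = 3)
  rain <- generate_rainfall(cfg)
  sc <- score_series(rain, lookback_years = 30)
  first <- sc[which.min(droughtimpact:::month_index(sc$year, sc$month)), ]
  expect_equal(first$year, 1969)
  expect_equal(first$month, 6)
  expect_equal(max(sc$year), 2007)
  # contiguous from the first scored month on
  expect_silent(droughtimpact:::check_contiguous(sc))
})

test_that("scores are scale invariant and bounded", {
  cfg <- sim_config(regions = tiny_regions()[1], start = c(1940, 1),
                    end = c(1990, 12), seed = 11)
  rain <- generate_rainfall(cfg)
  s1 <- score_series(rain)
  rain2 <- rain
  rain2$rain_mm <- rain2$rain_mm * 3.7
  s2 <- score_series(rain2)
  expect_equal(s1$score, s2$score)
  expect_true(all(s1$score >= -4 & s1$score <= 4))
})

test_that("a rainfall decline lowers scores relative to a flat era", {
  # flat climate 1940-1989, then a steady decline: months scored against
  # the wetter look-back years must come out drier on average
  n <- 80 * 12
  set.seed(5)
  base <- rgamma(n, 2, scale = 30)
  mult <- c(rep(1, 50 * 12), seq(1, 0.4, length.out = 30 * 12))
  sc <- score_series(scripted_rainfall(base * mult, start = c(1940, 1)))
  early <- sc$score[sc$year %in% 1970:1989]
  late <- sc$score[sc$year %in% 2000:2019]
  expect_lt(mean(late), mean(early))
})

test_that("drought state machine follows the -1 threshold rules", {
  # 6 months of mild drought then recovery: no full drought
  sc6 <- scripted_exposure(run_counters(6))
  sc6$counter <- NULL
  ex6 <- drought_counter(sc6[, c("region_id", "year", "month", "score")])
  expect_equal(sum(ex6$full_drought), 0)

  # 9 dry months: months 7-9 in full drought, counter 9, X = ln 10
  sc9 <- scripted_exposure(run_counters(9))
  ex9 <- drought_counter(sc9[, c("region_id", "year", "month", "score")])
  expect_equal(sum(ex9$full_drought), 3)
  expect_equal(max(ex9$counter), 9)
  expect_equal(max(ex9$X), log(10))
  # counter resets exactly when score > -1
  expect_true(all((ex9$counter == 0) == (ex9$score > -1)))

  # threshold is inclusive: score exactly -1 counts as dry
  sc1 <- data.frame(region_id = "A", year = 2000, month = 1:3,
                    score = c(-1, -1, 0))
  ex1 <- drought_counter(sc1)
  expect_equal(ex1$counter, c(1L, 2L, 0L))
})

test_that("constant rainfall yields zero drought months", {
  rain <- scripted_rainfall(rep(80, 45 * 12))
  ex <- drought_counter(score_series(rain))
  expect_equal(sum(ex$counter), 0)
  expect_equal(unique(ex$score), 0)
})

test_that("summarize_droughts tabulates spells and adds over periods", {
  none <- summarize_droughts(scripted_exposure(run_counters(5)))
  expect_equal(nrow(none$spells), 0)

  two <- scripted_exposure(c(run_counters(13, pre = 2, post = 4),
                             run_counters(31, pre = 0, post = 2)))
  sm <- summarize_droughts(two)
  expect_equal(nrow(sm$spells), 2)
  expect_equal(sm$spells$duration_reported, c(7, 25))
  expect_equal(sm$spells$n_mild_months, c(13, 31))
  expect_equal(sm$summary$max_duration, 25)

  # additivity over disjoint windows (split at a calm year boundary)
  y1 <- range(two$year)
  all_spells <- nrow(summarize_droughts(two)$spells)
  n_a <- nrow(summarize_droughts(two, period = c(y1[1], 1991))$spells)
  n_b <- nrow(summarize_droughts(two, period = c(1992, y1[2]))$spells)
  expect_equal(n_a + n_b, all_spells)
  expect_error(summarize_droughts(two, period = c(2050, 2060)), "empty")
})

test_that("exposure_iqr selects the configured month set", {
  ex <- scripted_exposure(run_counters(12, pre = 10, post = 10))
  expect_equal(exposure_iqr(ex, "all"),
               unname(diff(quantile(ex$X, c(.25, .75)))))
  expect_equal(exposure_iqr(ex, "full"),
               unname(diff(quantile(ex$X[ex$counter >= 7], c(.25, .75)))))
  calm <- scripted_exposure(rep(0, 12))
  expect_error(exposure_iqr(calm, "full"), "no months")
})
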