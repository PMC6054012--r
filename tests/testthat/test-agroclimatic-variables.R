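## a complete toy environment unit with hand-computable weather:
## FH Sep 1 - Oct 10 (40 d), WP Oct 11 - Apr 19, GP Apr 20 - Aug 25,
## cut1 Jun 18, cut2 Aug 25
toy_unit <- function() {
  data.frame(site_id = "S01", experiment_id = "E1", harvest_year = 2005,
             fh_start = as.Date("2004-09-01"), fh_end = as.Date("2004-10-10"),
             wp_start = as.Date("2004-10-11"), wp_end = as.Date("2005-04-19"),
             gp_start = as.Date("2005-04-20"), gp_end = as.Date("2005-08-25"),
             cut1 = as.Date("2005-06-18"), cut2 = as.Date("2005-08-25"),
             stringsAsFactors = FALSE)
}

## piecewise-constant weather over the unit's spans
toy_weather <- function() {
  w <- make_weather("2004-08-01", "2005-12-31", tmean = 0, tmin = 0,
                    tmax = 0, precip = 0)
  d <- w$date
  fh <- d >= as.Date("2004-09-01") & d <= as.Date("2004-10-10")
  wp <- d >= as.Date("2004-10-11") & d <= as.Date("2005-04-19")
  gp <- d >= as.Date("2005-04-20") & d <= as.Date("2005-08-25")
  w$tmean[fh] <- 3                     # 2 cold degree-days below 5 per day
  w$precip[fh] <- 1.46                 # 58.4 mm over the 40 days
  w$tmean[wp] <- rep(c(2, -2), length.out = sum(wp))  # alternating warm/cold
  w$tmin[wp] <- rep(c(-16, -3), length.out = sum(wp))
  w$tmean[gp] <- 15                    # 10 dd above 5 per day
  w$tmean[d > as.Date("2005-06-18") & d <= as.Date("2005-06-25")] <- 17.3
  w$tmax[gp] <- 20
  w$tmax[d >= as.Date("2005-05-01") & d <= as.Date("2005-05-03")] <- 26
  w$tmax[d >= as.Date("2005-07-01") & d <= as.Date("2005-07-04")] <- 29
  w$precip[gp] <- 2
  w
}

test_that("degree-day sums and day counts match their definitions", {
  w <- make_weather("2005-05-01", "2005-05-04", tmean = c(3, 4, 6, 2))
  span <- list(start = "2005-05-01", end = "2005-05-04")
  expect_equal(degree_day_sum(w, span, 5, "below"), 6)  # 2+1+0+3
  expect_equal(degree_day_sum(w, span, 5, "above"), 1)

  w2 <- make_weather("2005-01-01", "2005-01-03", tmean = 0,
                     tmin = c(-16, -15, -14))
  sp2 <- list(start = "2005-01-01", end = "2005-01-03")
  expect_equal(count_days(w2, sp2, "tmin", -15, "le"), 2)
  expect_equal(count_days(w2, sp2, "tmin", -20, "le"), 0)
})

test_that("vectorised aggregations equal a naive per-day loop on random series", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 30
    w <- make_weather("2005-06-01", "2005-06-30",
                      tmean = round(rnorm(n, 10, 6), 1))
    w$tmax <- w$tmean + round(runif(n, 0, 8), 1)
    span <- list(start = "2005-06-01", end = "2005-06-30")
    loop_above <- 0
    loop_count <- 0
    for (i in 1:n) {
      loop_above <- loop_above + max(0, w$tmean[i] - 5)
      if (w$tmax[i] >= 25) loop_count <- loop_count + 1
    }
    expect_equal(degree_day_sum(w, span, 5, "above"), loop_above)
    expect_equal(count_days(w, span, "tmax", 25, "ge"), loop_count)
  }
})

test_that("all 14 variables match hand-computed values on the toy unit", {
  u <- toy_unit()
  w <- toy_weather()
  v <- compute_all_variables(u, w)
  expect_equal(v$FH_LENGTH, 40)
  expect_equal(v$FH_COLD5, 80)          # 40 days x 2 dd
  expect_equal(v$FH_RAIN, 1.46)         # 58.4 mm / 40 d
  ## WP alternates +2/-2 from Oct 11: 191 days, 96 warm days x 2 dd
  expect_equal(v$WP_WARM0_RATE, 96 * 2 / 191)
  expect_equal(v$WP_STRESS15, 96)       # alternating -16 days
  ## GP Apr 20-Aug 25 = 128 d at 10 dd, 7 post-cut days at 17.3 replace 15
  expect_equal(v$GP_TSUM5, 128 * 10 + 7 * (12.3 - 10))
  expect_equal(v$GP_TSUM_RATE, v$GP_TSUM5 / 128)
  expect_equal(v$GP_HOT25_CUT1, 3)      # May 1-3
  expect_equal(v$GP_HOT25_CUT2, 4)      # Jul 1-4
  expect_equal(v$GP_HOT28, 4)           # only the 29 degC days
  expect_equal(v$GP_POSTCUT_TSUM7, 121.1)  # 7 x 17.3
  expect_equal(v$GP_RAIN_CUT1, 60 * 2)  # Apr 20-Jun 18 = 60 d x 2 mm
  expect_equal(v$GP_RAIN_CUT2, 68 * 2)  # Jun 19-Aug 25 = 68 d x 2 mm
  expect_equal(v$GP_POSTCUT_RAIN14, 28) # 14 d x 2 mm
})

test_that("absent spans yield missing values with reasons, never silent zeros", {
  u <- toy_unit()
  u$fh_start <- u$fh_end <- u$wp_start <- u$wp_end <- as.Date(NA)
  w <- toy_weather()
  res <- compute_variable(u, w, "FH_COLD5")
  expect_true(is.na(res$value))
  expect_equal(res$reason, "fh_absent")
  expect_equal(compute_variable(u, w, "WP_STRESS15")$reason, "wp_absent")
  ## GP variables unaffected
  expect_false(is.na(compute_variable(u, w, "GP_TSUM5")$value))

  u2 <- toy_unit()
  u2$cut2 <- as.Date(NA)
  v2 <- compute_all_variables(u2, w)
  expect_equal(v2$reason_GP_HOT25_CUT2, "cut2_absent")
  expect_equal(v2$reason_GP_RAIN_CUT2, "cut2_absent")
  expect_false(is.na(v2$GP_HOT25_CUT1))
})

test_that("batch computation equals per-unit single calls column by column", {
  set.seed(17)
  w <- generate_weather(weather_gen_config(seed = 23), "S01", 2005:2006)
  units <- do.call(rbind, lapply(2005:2006, function(y) {
    seg <- segment_season(w, y, as.Date(sprintf("%d-08-25", y)))
    data.frame(site_id = "S01", experiment_id = "E1", harvest_year = y,
               fh_start = seg$fh$start, fh_end = seg$fh$end,
               wp_start = seg$wp$start, wp_end = seg$wp$end,
               gp_start = seg$gp$start, gp_end = seg$gp$end,
               cut1 = as.Date(sprintf("%d-06-20", y)),
               cut2 = as.Date(sprintf("%d-08-25", y)))
  }))
  batch <- compute_all_variables(units, w)
  for (id in acv_registry()$id) {
    singles <- vapply(seq_len(nrow(units)), function(i) {
      compute_variable(units[i, ], w, id)$value
    }, numeric(1))
    expect_equal(batch[[id]], singles, info = id)
  }
})

test_that("degree-day sums are additive over adjacent spans and rates rescale", {
  w <- generate_weather(weather_gen_config(seed = 31), "S01", 2005)
  a <- list(start = as.Date("2005-05-01"), end = as.Date("2005-06-15"))
  b <- list(start = as.Date("2005-06-16"), end = as.Date("2005-08-01"))
  ab <- list(start = a$start, end = b$end)
  expect_equal(degree_day_sum(w, a, 5, "above") + degree_day_sum(w, b, 5, "above"),
               degree_day_sum(w, ab, 5, "above"))

  u <- toy_unit(); tw <- toy_weather()
  v <- compute_all_variables(u, tw)
  expect_equal(v$FH_RAIN * v$FH_LENGTH, sum(tw$precip[
    tw$date >= u$fh_start & tw$date <= u$fh_end]))
  gp_len <- as.numeric(u$gp_end - u$gp_start) + 1
  expect_equal(v$GP_TSUM_RATE * gp_len, v$GP_TSUM5)
  ## counts bounded by span length, precipitation non-negative
  expect_lte(v$WP_STRESS15, as.numeric(u$wp_end - u$wp_start) + 1)
  expect_true(all(c(v$FH_RAIN, v$GP_RAIN_CUT1, v$GP_RAIN_CUT2,
                    v$GP_POSTCUT_RAIN14) >= 0))
})

test_that("the registry enumerates exactly the 14 variables with valid fields", {
  reg <- acv_registry()
  expect_equal(nrow(reg), 14)
  expect_false(anyDuplicated(reg$id) > 0)
  expect_setequal(unique(reg$period), c("FH", "WP", "GP"))
  expect_true(all(reg$aggregation %in%
    c("span_length", "dd_below", "dd_above", "dd_above_rate", "mean_daily",
      "sum", "count_ge", "count_le")))
})
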