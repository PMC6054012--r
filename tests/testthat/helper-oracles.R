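## Independent brute-force oracles and fixture builders.  Each oracle is a
## literal, day-by-day (or partition-by-partition) restatement of the rule
## it checks, deliberately written without reusing package internals.

## Build a single-site weather frame from vectors (recycled to the dates).
make_weather <- function(from, to, tmean, tmin = tmean - 4, tmax = tmean + 4,
                         precip = 0, site_id = "S01") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  data.frame(site_id = site_id, date = dates,
             tmean = rep_len(tmean, length(dates)),
             tmin = rep_len(tmin, length(dates)),
             tmax = rep_len(tmax, length(dates)),
             precip = rep_len(precip, length(dates)),
             stringsAsFactors = FALSE)
}

## Literal fall-hardening scan: for every candidate day recompute the
## floored cold/warm balance from 1 August from scratch, then walk the
## frost rule forward.  O(n^2) on purpose.
oracle_fall_hardening <- function(weather, season_year) {
  from <- as.Date(sprintf("%d-08-01", season_year - 1))
  to <- as.Date(sprintf("%d-04-30", season_year))
  w <- weather[weather$date >= from & weather$date <= to, ]
  n <- nrow(w)
  balance_on <- function(d) {
    b <- 0
    for (i in 1:d) {
      b <- b + max(0, 5 - w$tmean[i]) - max(0, w$tmean[i] - 5)
      if (b < 0) b <- 0
    }
    b
  }
  start <- NA_integer_
  for (d in 1:n) if (balance_on(d) <= 0) start <- d
  if (is.na(start)) start <- 1L

  frost_days <- which(w$tmin <= -10)
  flags <- character(0)
  if (length(frost_days) && frost_days[1] < start) {
    return(list(start = as.Date(NA), end = as.Date(NA),
                flags = "fh_degenerate"))
  }
  if (!length(frost_days)) {
    flags <- "fh_no_frost_capped"
    if (start == n) {
      return(list(start = as.Date(NA), end = as.Date(NA),
                  flags = c(flags, "fh_degenerate")))
    }
    end <- n
  } else {
    end <- frost_days[1]
    while ((end + 1) %in% frost_days) end <- end + 1
  }
  list(start = w$date[start], end = w$date[end], flags = flags)
}

## Literal growth-period-start scan over all 5-day windows.
oracle_gp_start <- function(weather, season_year) {
  from <- as.Date(sprintf("%d-01-01", season_year))
  to <- as.Date(sprintf("%d-07-31", season_year))
  w <- weather[weather$date >= from & weather$date <= to, ]
  for (d in 5:nrow(w)) {
    if (all(w$tmean[(d - 4):d] > 5)) return(w$date[d])
  }
  as.Date(NA)
}

## Exhaustive contiguous-partition oracle for observation-balanced
## tertiles: enumerate every pair of break positions between units in
## value order, discard partitions that split a tie block, and return the
## minimal achievable max deviation from N/3.
oracle_tertile_best_dev <- function(values, n_obs) {
  ord <- order(values)
  values <- values[ord]; n_obs <- n_obs[ord]
  n <- length(values)
  N <- sum(n_obs)
  best <- Inf
  for (i in 1:(n - 2)) {
    if (values[i] == values[i + 1]) next  # would split a tie block
    for (j in (i + 1):(n - 1)) {
      if (values[j] == values[j + 1]) next
      cnt <- c(sum(n_obs[1:i]), sum(n_obs[(i + 1):j]), sum(n_obs[(j + 1):n]))
      best <- min(best, max(abs(cnt - N / 3)))
    }
  }
  best
}

## Direct (weather-free) simulation of the cultivar x category mixed-model
## design used in the calibration studies: 6 cultivars x 30 units (10 per
## category), sigma_unit = 1000, sigma_eps = 400, cultivar and category
## main effects planted, interaction of configurable response range.
simulate_gxe_design <- function(seed, response_range = 0, n_cultivars = 6,
                                n_units = 30, sigma_unit = 1000,
                                sigma_eps = 400) {
  set.seed(seed)
  stopifnot(n_units %% 3 == 0)
  units <- sprintf("U%02d", seq_len(n_units))
  cat_of_unit <- rep(c("low", "moderate", "high"), each = n_units / 3)
  cultivars <- sprintf("CV%02d", seq_len(n_cultivars))
  d <- expand.grid(cultivar = cultivars, unit_id = units,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$category <- factor(cat_of_unit[match(d$unit_id, units)],
                       levels = c("low", "moderate", "high"))
  g <- rnorm(n_cultivars, 0, 300)
  e <- c(-500, 0, 500)
  resp <- if (response_range > 0) {
    seq(-response_range / 2, response_range / 2, length.out = n_cultivars)
  } else rep(0, n_cultivars)
  x <- c(-0.5, 0, 0.5)
  u <- rnorm(n_units, 0, sigma_unit)
  ci <- match(d$cultivar, cultivars)
  cj <- as.integer(d$category)
  d$annual_dm_yield <- 7000 + g[ci] + e[cj] + resp[ci] * x[cj] +
    u[match(d$unit_id, units)] + rnorm(nrow(d), 0, sigma_eps)
  d
}
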