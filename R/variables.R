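#' Registry of the 14 agroclimatic variables
#'
#' Machine-readable description of every agroclimatic variable the package
#' computes: its period (fall hardening FH, winter WP or growth period GP),
#' the temperature or precipitation field it aggregates, the threshold or
#' base involved, the aggregation rule and the units.  Tests enumerate this
#' registry rather than hard-coding the variable list.
#'
#' @return Data frame with columns `id`, `period`, `window`, `field`,
#'   `threshold`, `aggregation`, `units`, `description`.
#' @export
acv_registry <- function() {
  reg <- rbind(
    c("FH_LENGTH",         "FH", "fh",          "",       NA, "span_length", "days",
      "Length of the fall-hardening period"),
    c("FH_COLD5",          "FH", "fh",          "tmean",   5, "dd_below",    "degree-days",
      "Accumulation of cold temperatures below 5 degC during FH"),
    c("FH_RAIN",           "FH", "fh",          "precip", NA, "mean_daily",  "mm/day",
      "Mean daily rainfall during FH"),
    c("WP_WARM0_RATE",     "WP", "wp",          "tmean",   0, "dd_above_rate", "degree-days/day",
      "Mean daily accumulation of temperature above 0 degC during WP"),
    c("WP_STRESS15",       "WP", "wp",          "tmin",  -15, "count_le",    "days",
      "Cold stress days with minimum temperature at or below -15 degC during WP"),
    c("GP_TSUM5",          "GP", "gp",          "tmean",   5, "dd_above",    "degree-days",
      "Temperature sum above 5 degC over the growth period"),
    c("GP_TSUM_RATE",      "GP", "gp",          "tmean",   5, "dd_above_rate", "degree-days/day",
      "Mean daily temperature-sum accumulation rate over the growth period"),
    c("GP_HOT25_CUT1",     "GP", "gp_to_cut1",  "tmax",   25, "count_ge",    "days",
      "Days with maximum temperature of at least 25 degC, GP start to 1st cut"),
    c("GP_HOT25_CUT2",     "GP", "cut1_to_cut2","tmax",   25, "count_ge",    "days",
      "Days with maximum temperature of at least 25 degC, 1st cut to 2nd cut"),
    c("GP_HOT28",          "GP", "gp",          "tmax",   28, "count_ge",    "days",
      "Days with maximum temperature of at least 28 degC over the growth period"),
    c("GP_POSTCUT_TSUM7",  "GP", "cut1_plus7",  "tmean",   0, "dd_above",    "degree-days",
      "Temperature sum (positive daily means) over the 7 days after the 1st cut"),
    c("GP_RAIN_CUT1",      "GP", "gp_to_cut1",  "precip", NA, "sum",         "mm",
      "Precipitation from GP start to the 1st cut"),
    c("GP_RAIN_CUT2",      "GP", "cut1_to_cut2","precip", NA, "sum",         "mm",
      "Precipitation from the 1st cut to the 2nd cut"),
    c("GP_POSTCUT_RAIN14", "GP", "cut1_plus14", "precip", NA, "sum",         "mm",
      "Precipitation over the 14 days after the 1st cut")
  )
  out <- as.data.frame(reg, stringsAsFactors = FALSE)
  names(out) <- c("id", "period", "window", "field", "threshold",
                  "aggregation", "units", "description")
  out$threshold <- as.numeric(out$threshold)
  out
}

#' Degree-day sum over a period
#'
#' Sums daily exceedances above, or deficits below, a base temperature over
#' an inclusive date span.
#'
#' @param weather daily weather data frame for one site.
#' @param span list or vector with `start` and `end` dates (inclusive).
#' @param base base temperature, degC.
#' @param direction `"above"` sums `max(0, tmean - base)` per day;
#'   `"below"` sums `max(0, base - tmean)`.
#' @return Degree-day sum (numeric, >= 0).
#' @export
degree_day_sum <- function(weather, span, base, direction = c("above", "below")) {
  direction <- match.arg(direction)
  w <- weather_window(weather, site_id = NULL,
                      from = as.Date(span$start), to = as.Date(span$end))
  if (direction == "above") sum(pmax(0, w$tmean - base))
  else sum(pmax(0, base - w$tmean))
}

#' Count days meeting a temperature condition over a period
#'
#' @inheritParams degree_day_sum
#' @param field `"tmin"` or `"tmax"`.
#' @param threshold temperature threshold, degC.
#' @param cmp `"ge"` counts days with field >= threshold; `"le"` days with
#'   field <= threshold.
#' @return Integer count in `[0, span length]`.
#' @export
count_days <- function(weather, span, field = c("tmin", "tmax"),
                       threshold, cmp = c("ge", "le")) {
  field <- match.arg(field)
  cmp <- match.arg(cmp)
  w <- weather_window(weather, site_id = NULL,
                      from = as.Date(span$start), to = as.Date(span$end))
  x <- w[[field]]
  if (cmp == "ge") sum(x >= threshold) else sum(x <= threshold)
}

## Resolve the date window an agroclimatic variable aggregates over for one
## environment unit, or return a missingness reason.  Windows anchored on
## the cuts start the day AFTER the cut ("after 1st cut"); the primary
## growth window includes the cut day itself.
acv_window <- function(unit, window) {
  need <- function(ok, reason) if (ok) NULL else reason
  switch(window,
    fh = {
      r <- need(!is.na(unit$fh_start), "fh_absent")
      if (!is.null(r)) return(r)
      list(start = unit$fh_start, end = unit$fh_end)
    },
    wp = {
      r <- need(!is.na(unit$wp_start), "wp_absent")
      if (!is.null(r)) return(r)
      list(start = unit$wp_start, end = unit$wp_end)
    },
    gp = {
      r <- need(!is.na(unit$gp_start), "gp_absent")
      if (!is.null(r)) return(r)
      list(start = unit$gp_start, end = unit$gp_end)
    },
    gp_to_cut1 = {
      r <- need(!is.na(unit$gp_start), "gp_absent")
      if (!is.null(r)) return(r)
      r <- need(!is.na(unit$cut1), "cut1_absent")
      if (!is.null(r)) return(r)
      list(start = unit$gp_start, end = unit$cut1)
    },
    cut1_to_cut2 = {
      r <- need(!is.na(unit$cut1), "cut1_absent")
      if (!is.null(r)) return(r)
      r <- need(!is.na(unit$cut2), "cut2_absent")
      if (!is.null(r)) return(r)
      list(start = unit$cut1 + 1L, end = unit$cut2)
    },
    cut1_plus7 = {
      r <- need(!is.na(unit$cut1), "cut1_absent")
      if (!is.null(r)) return(r)
      list(start = unit$cut1 + 1L, end = unit$cut1 + 7L)
    },
    cut1_plus14 = {
      r <- need(!is.na(unit$cut1), "cut1_absent")
      if (!is.null(r)) return(r)
      list(start = unit$cut1 + 1L, end = unit$cut1 + 14L)
    },
    stop("unknown window: ", window)
  )
}

#' Compute one agroclimatic variable for one environment unit
#'
#' An environment unit is one site x harvest-year x experiment season with
#' its period segmentation and cut schedule.  A variable whose period span
#' is absent (for example FH variables after a degenerate autumn, or
#' second-cut variables when only one regrowth cut was taken) is returned
#' missing with an explicit reason, never as a silent zero.
#'
#' @param unit a one-row data frame (or list) with fields `fh_start`,
#'   `fh_end`, `wp_start`, `wp_end`, `gp_start`, `gp_end`, `cut1`, `cut2`
#'   (dates, `NA` where absent).
#' @param weather daily weather data frame for the unit's site.
#' @param id a variable id from [acv_registry()].
#' @return A list with `value` (numeric or `NA`) and `reason`
#'   (`NA_character_` when the value is present).
#' @export
compute_variable <- function(unit, weather, id) {
  reg <- acv_registry()
  row <- reg[reg$id == id, ]
  if (nrow(row) != 1L) stop("unknown agroclimatic variable id: ", id)

  win <- acv_window(unit, row$window)
  if (is.character(win)) return(list(value = NA_real_, reason = win))

  val <- tryCatch({
    switch(row$aggregation,
      span_length = as.numeric(win$end - win$start) + 1,
      dd_below = degree_day_sum(weather, win, row$threshold, "below"),
      dd_above = degree_day_sum(weather, win, row$threshold, "above"),
      dd_above_rate = {
        len <- as.numeric(win$end - win$start) + 1
        degree_day_sum(weather, win, row$threshold, "above") / len
      },
      mean_daily = {
        w <- weather_window(weather, NULL, win$start, win$end)
        sum(w$precip) / nrow(w)
      },
      sum = {
        w <- weather_window(weather, NULL, win$start, win$end)
        sum(w$precip)
      },
      count_ge = count_days(weather, win, row$field, row$threshold, "ge"),
      count_le = count_days(weather, win, row$field, row$threshold, "le"),
      stop("unknown aggregation: ", row$aggregation))
  }, incomplete_weather = function(e) e)
  if (inherits(val, "condition")) {
    return(list(value = NA_real_, reason = "incomplete_weather"))
  }
  list(value = val, reason = NA_character_)
}

#' Compute all 14 agroclimatic variables for a set of environment units
#'
#' @param units data frame with one row per environment unit: `site_id`,
#'   `experiment_id`, `harvest_year`, the segmentation columns of
#'   [segment_seasons()] and cut dates `cut1`, `cut2` (`NA` when only one
#'   regrowth cut was taken).
#' @param weather daily weather data frame covering every unit's site.
#' @param ids variable ids to compute (default: the full registry).
#' @return Data frame with the unit key columns, one numeric column per
#'   variable and one `reason_<id>` column per variable recording why a
#'   value is missing.  The attribute `"flag_counts"` tallies missingness
#'   reasons across the table.
#' @export
compute_all_variables <- function(units, weather, ids = acv_registry()$id) {
  if (!all(units$site_id %in% weather$site_id)) {
    stop("no weather for site(s): ",
         paste(setdiff(units$site_id, weather$site_id), collapse = ", "))
  }
  out <- units[, c("site_id", "experiment_id", "harvest_year"), drop = FALSE]
  reasons <- character(0)
  for (id in ids) {
    vals <- numeric(nrow(units))
    reas <- character(nrow(units))
    for (i in seq_len(nrow(units))) {
      w <- weather[weather$site_id == units$site_id[i], , drop = FALSE]
      res <- compute_variable(units[i, ], w, id)
      vals[i] <- res$value
      reas[i] <- res$reason
    }
    out[[id]] <- vals
    out[[paste0("reason_", id)]] <- reas
    reasons <- c(reasons, reas[!is.na(reas)])
  }
  attr(out, "flag_counts") <- if (length(reasons)) table(reasons) else table(character(0))
  out
}

#' Write an agroclimatic-variable table to CSV
#'
#' @param variables data frame from [compute_all_variables()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variables_csv <- function(variables, path) {
  utils::write.csv(variables, path, row.names = FALSE, na = "")
  invisible(path)
}
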