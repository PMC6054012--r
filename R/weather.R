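#' Read a daily weather CSV
#'
#' Reads per-site daily weather records with columns `site_id`,
#' `date` (ISO-8601 `YYYY-MM-DD`), `tmean_c`, `tmin_c`, `tmax_c` and
#' `precip_mm`.  Duplicate site-days are rejected: a station reports one
#' record per day, so duplicates indicate a corrupted extract.
#'
#' @param path path to the CSV file.
#' @return A data frame with columns `site_id`, `date` (`Date`), `tmean`,
#'   `tmin`, `tmax`, `precip`, ordered by site and date.
#' @export
read_weather_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "date", "tmean_c", "tmin_c", "tmax_c", "precip_mm")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("weather CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  w <- data.frame(
    site_id = as.character(raw$site_id),
    date    = as.Date(raw$date),
    tmean   = as.numeric(raw$tmean_c),
    tmin    = as.numeric(raw$tmin_c),
    tmax    = as.numeric(raw$tmax_c),
    precip  = as.numeric(raw$precip_mm),
    stringsAsFactors = FALSE
  )
  if (anyNA(w$date)) stop("weather CSV contains unparseable dates")
  key <- paste(w$site_id, w$date)
  if (anyDuplicated(key)) {
    stop("duplicate site-day records in weather CSV: ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  }
  w[order(w$site_id, w$date), , drop = FALSE]
}

## Extract one site's records for an inclusive date window, insisting on
## full contiguous coverage.  Missing days are an error (class
## "incomplete_weather"), never silently skipped: every downstream
## aggregation assumes daily resolution.
weather_window <- function(weather, site_id = NULL, from, to) {
  w <- weather
  if (!is.null(site_id)) w <- w[w$site_id == site_id, , drop = FALSE]
  w <- w[w$date >= from & w$date <= to, , drop = FALSE]
  wanted <- seq(from, to, by = "day")
  if (nrow(w) != length(wanted) || !all(w$date == wanted)) {
    missing_days <- setdiff(as.character(wanted), as.character(w$date))
    stop(structure(
      class = c("incomplete_weather", "error", "condition"),
      list(message = sprintf(
        "incomplete weather for site '%s': window %s..%s lacks %d day(s) (first: %s)",
        if (is.null(site_id)) unique(weather$site_id)[1] else site_id,
        format(from), format(to), length(missing_days),
        if (length(missing_days)) missing_days[1] else "?"),
        call = NULL)))
  }
  w
}

#' Find the fall-hardening period of one season
#'
#' The fall-hardening (FH) period of a season starts on the last day,
#' counting from 1 August of the preceding calendar year, on which the
#' running balance of cold degree-days below 5 degC minus degree-days above
#' 5 degC is still zero, and ends on the last day of the first spell of
#' days with minimum air temperature at or below -10 degC.  The balance is
#' floored at zero — summer warmth cannot bank a deficit against autumn
#' cold — so FH starts on the day cold accumulation permanently overtakes
#' warmth, the convention of the fall-hardening literature.  If the balance
#' is already positive on 1 August (a cold start to autumn), FH starts on
#' 1 August.
#'
#' Two irregular winters are handled explicitly rather than failing the
#' season.  When no frost day at or below -10 degC occurs before 30 April,
#' the end is capped at 30 April and the flag `fh_no_frost_capped` is set.
#' When the first frost spell falls before the computed start (or the cold
#' balance never settles above zero at all), hardening is undefined: the
#' span is reported absent with flag `fh_degenerate`.
#'
#' @param weather daily weather data frame (see [read_weather_csv()]) for
#'   one site; must cover 1 August of `season_year - 1` through 30 April of
#'   `season_year`.
#' @param season_year calendar year of the growth period; the FH searched
#'   for lies in the preceding autumn.
#' @return A list with elements `start`, `end` (`Date` or `NA` when the span
#'   is absent) and `flags` (character vector).
#' @export
find_fall_hardening <- function(weather, season_year) {
  from <- as.Date(sprintf("%d-08-01", season_year - 1L))
  to <- as.Date(sprintf("%d-04-30", season_year))
  w <- weather_window(weather, site_id = NULL, from = from, to = to)

  ## running cold/warm degree-day balance from 1 August, floored at zero
  inc <- pmax(0, 5 - w$tmean) - pmax(0, w$tmean - 5)
  bal <- numeric(length(inc))
  b <- 0
  for (i in seq_along(inc)) {
    b <- max(0, b + inc[i])
    bal[i] <- b
  }
  at_or_below <- which(bal <= 0)
  start_idx <- if (length(at_or_below)) max(at_or_below) else 1L

  flags <- character(0)
  frost <- w$tmin <= -10
  first_frost <- if (any(frost)) which(frost)[1] else NA_integer_

  if (!is.na(first_frost) && first_frost < start_idx) {
    ## frost arrived before the cold balance caught up: hardening undefined
    return(list(start = as.Date(NA), end = as.Date(NA),
                flags = "fh_degenerate"))
  }

  if (is.na(first_frost)) {
    flags <- c(flags, "fh_no_frost_capped")
    if (start_idx == nrow(w)) {
      ## balance never returned to zero either; nothing resembling FH
      return(list(start = as.Date(NA), end = as.Date(NA),
                  flags = c(flags, "fh_degenerate")))
    }
    end_idx <- nrow(w)
  } else {
    ## last day of the first consecutive frost run
    end_idx <- first_frost
    while (end_idx < nrow(w) && frost[end_idx + 1L]) end_idx <- end_idx + 1L
  }

  list(start = w$date[start_idx], end = w$date[end_idx], flags = flags)
}

#' Find the growth-period start of one season
#'
#' The growth period (GP) starts on the fifth day of the first spell of at
#' least five consecutive days with daily mean air temperature above
#' 5 degC, searching from 1 January of `season_year`.
#'
#' @inheritParams find_fall_hardening
#' @param weather daily weather for one site covering 1 January through
#'   31 July of `season_year`.
#' @return A list with `date` (`Date`, `NA` when no qualifying spell exists
#'   by 31 July) and `flags` (contains `"no_gp_spell"` in that case).
#' @export
find_growth_period_start <- function(weather, season_year) {
  from <- as.Date(sprintf("%d-01-01", season_year))
  to <- as.Date(sprintf("%d-07-31", season_year))
  w <- weather_window(weather, site_id = NULL, from = from, to = to)

  warm <- w$tmean > 5
  run <- 0L
  for (i in seq_along(warm)) {
    run <- if (warm[i]) run + 1L else 0L
    if (run == 5L) {
      return(list(date = w$date[i], flags = character(0)))
    }
  }
  list(date = as.Date(NA), flags = "no_gp_spell")
}

#' Segment one site-season into fall-hardening, winter and growth periods
#'
#' Composes [find_fall_hardening()] and [find_growth_period_start()].  The
#' winter period (WP) runs from the day after FH ends to the day before the
#' GP starts; the GP ends with the last harvest of the season.  When FH is
#' absent (degenerate autumn) the WP is absent too, but the GP is still
#' computed so growth-period variables remain available.
#'
#' @inheritParams find_fall_hardening
#' @param last_harvest `Date` of the season's last cut; must fall on or
#'   after the GP start.
#' @return A list of class `season_segmentation` with elements `site_id`,
#'   `season_year`, `fh`, `wp`, `gp` (each `NULL` or a list with `start`,
#'   `end`) and `flags`.
#' @export
segment_season <- function(weather, season_year, last_harvest) {
  site_id <- unique(weather$site_id)
  if (length(site_id) != 1L) stop("segment_season() expects one site")
  last_harvest <- as.Date(last_harvest)

  fh <- find_fall_hardening(weather, season_year)
  gp <- find_growth_period_start(weather, season_year)
  flags <- union(fh$flags, gp$flags)

  fh_span <- if (!is.na(fh$start)) list(start = fh$start, end = fh$end)
  gp_span <- NULL
  if (!is.na(gp$date)) {
    if (last_harvest < gp$date) {
      stop(sprintf(
        "site '%s', season %d: last harvest (%s) precedes growth-period start (%s)",
        site_id, season_year, format(last_harvest), format(gp$date)))
    }
    gp_span <- list(start = gp$date, end = last_harvest)
  }

  wp_span <- NULL
  if (!is.null(fh_span) && !is.null(gp_span)) {
    wp_start <- fh_span$end + 1L
    wp_end <- gp_span$start - 1L
    if (wp_start <= wp_end) {
      wp_span <- list(start = wp_start, end = wp_end)
    } else {
      flags <- union(flags, "fh_degenerate")
    }
  }

  structure(list(site_id = site_id, season_year = season_year,
                 fh = fh_span, wp = wp_span, gp = gp_span,
                 flags = sort(flags)),
            class = "season_segmentation")
}

#' Segment a batch of site-seasons
#'
#' Applies [segment_season()] to each requested site-season and collects
#' the spans into one table.  A season whose weather coverage is incomplete
#' is not dropped: its spans are reported absent with flag
#' `incomplete_weather`, so downstream variable computation can record the
#' reason.
#'
#' @param weather daily weather data frame, possibly covering several sites.
#' @param seasons data frame with columns `site_id`, `season_year`,
#'   `last_harvest` (`Date`).
#' @return Data frame with one row per season: `site_id`, `season_year`,
#'   `fh_start`, `fh_end`, `wp_start`, `wp_end`, `gp_start`, `gp_end`
#'   (`Date`, `NA` for absent spans) and `flags` (semicolon-separated).
#' @export
segment_seasons <- function(weather, seasons) {
  span_or_na <- function(span, which) {
    if (is.null(span)) as.Date(NA) else span[[which]]
  }
  rows <- lapply(seq_len(nrow(seasons)), function(i) {
    s <- seasons[i, ]
    w <- weather[weather$site_id == s$site_id, , drop = FALSE]
    seg <- tryCatch(
      segment_season(w, s$season_year, s$last_harvest),
      incomplete_weather = function(e) {
        structure(list(site_id = s$site_id, season_year = s$season_year,
                       fh = NULL, wp = NULL, gp = NULL,
                       flags = "incomplete_weather"),
                  class = "season_segmentation")
      })
    data.frame(site_id = s$site_id, season_year = s$season_year,
               fh_start = span_or_na(seg$fh, "start"),
               fh_end   = span_or_na(seg$fh, "end"),
               wp_start = span_or_na(seg$wp, "start"),
               wp_end   = span_or_na(seg$wp, "end"),
               gp_start = span_or_na(seg$gp, "start"),
               gp_end   = span_or_na(seg$gp, "end"),
               flags = paste(seg$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a segmentation table to CSV
#'
#' @param segmentation data frame from [segment_seasons()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segmentation_csv <- function(segmentation, path) {
  out <- segmentation
  for (col in c("fh_start", "fh_end", "wp_start", "wp_end",
                "gp_start", "gp_end")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
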