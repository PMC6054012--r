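#' Read a variety-trial CSV
#'
#' Columns: `site_id`, `experiment_id`, `harvest_year`, `species`,
#' `cultivar`, `origin`, `annual_dm_yield_kg_ha`, `cut1_date`, `cut2_date`,
#' `last_cut_date` (ISO-8601, empty cell = missing).  Annual dry-matter
#' yield is the sum over all cuts of one season, kg DM/ha/year.
#'
#' @param path path to the CSV file.
#' @return Data frame with parsed dates (`cut1`, `cut2`, `last_cut`) and a
#'   numeric `annual_dm_yield` column.
#' @export
read_trials_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site_id", "experiment_id", "harvest_year", "species",
            "cultivar", "origin", "annual_dm_yield_kg_ha",
            "cut1_date", "cut2_date", "last_cut_date")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("trial CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  parse_date <- function(x) as.Date(ifelse(!nzchar(trimws(x)), NA, x))
  data.frame(
    site_id = raw$site_id,
    experiment_id = raw$experiment_id,
    harvest_year = as.integer(raw$harvest_year),
    species = raw$species,
    cultivar = raw$cultivar,
    origin = raw$origin,
    annual_dm_yield = as.numeric(raw$annual_dm_yield_kg_ha),
    cut1 = parse_date(raw$cut1_date),
    cut2 = parse_date(raw$cut2_date),
    last_cut = parse_date(raw$last_cut_date),
    stringsAsFactors = FALSE
  )
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials_csv()].
#'
#' @param trials trial data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  fmt <- function(d) ifelse(is.na(d), "", format(d))
  out <- data.frame(
    site_id = trials$site_id,
    experiment_id = trials$experiment_id,
    harvest_year = trials$harvest_year,
    species = trials$species,
    cultivar = trials$cultivar,
    origin = trials$origin,
    annual_dm_yield_kg_ha = trials$annual_dm_yield,
    cut1_date = fmt(trials$cut1),
    cut2_date = fmt(trials$cut2),
    last_cut_date = fmt(trials$last_cut),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute missing cut dates from the rest of the trial network
#'
#' A handful of harvest dates are typically missing from multi-site trial
#' archives.  They are imputed on the day-of-year scale with a linear mixed
#' model carrying species and cut-number fixed effects and a random
#' site-by-year intercept, so each imputed date borrows mainly from the
#' harvest dates of the other cultivars cut at the same site and year.
#' Predictions are rounded to whole days and clamped inside the range of
#' observed harvest days at that site-year.
#'
#' A site-year in which no cultivar has an observed date for the needed cut
#' offers no donor information; such observations are flagged
#' (`cuts_incomplete = TRUE`) and excluded from agroclimatic-variable
#' computation rather than guessed at.
#'
#' @param trials trial data frame (see [read_trials_csv()]).
#' @return A list with `trials` (dates filled in, plus a logical
#'   `cuts_incomplete` column) and `log` (one row per imputed value:
#'   row index, field, imputed date, number of donor records at the
#'   site-year).
#' @export
impute_missing_cut_dates <- function(trials) {
  tr <- trials
  tr$cuts_incomplete <- FALSE
  fields <- c("cut1", "cut2", "last_cut")

  ## long table of all cut dates as day-of-year
  long <- do.call(rbind, lapply(fields, function(f) {
    data.frame(row = seq_len(nrow(tr)),
               field = f,
               site_year = paste(tr$site_id, tr$harvest_year, sep = ":"),
               species = tr$species,
               doy = as.integer(format(tr[[f]], "%j")),
               year = tr$harvest_year,
               stringsAsFactors = FALSE)
  }))
  ## cut2 genuinely absent (two-cut season) is not "missing": only treat a
  ## cut2 as missing when last_cut is a later, distinct date (3-cut season)
  ## or when it was explicitly masked relative to the schedule; here we
  ## impute any NA cut1/last_cut, and NA cut2 only for rows where some
  ## other observation of the same experiment has a cut2.
  exp_key <- paste(tr$site_id, tr$harvest_year, tr$experiment_id, sep = ":")
  has_cut2 <- tapply(!is.na(tr$cut2), exp_key, any)[exp_key]
  target <- is.na(long$doy) &
    (long$field != "cut2" | has_cut2[long$row])

  if (!any(target)) {
    return(list(trials = tr,
                log = data.frame(row = integer(0), field = character(0),
                                 imputed = as.Date(character(0)),
                                 n_donors = integer(0))))
  }

  obs <- long[!is.na(long$doy), , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observed cut dates to impute from")

  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      doy ~ species + field + (1 | site_year),
      data = obs,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = lme4::.makeCC(
                                    action = "ignore", tol = 1e-4)))),
    error = function(e) NULL)

  log_rows <- list()
  for (k in which(target)) {
    li <- long[k, ]
    donors <- obs[obs$site_year == li$site_year & obs$field == li$field, ]
    if (nrow(donors) == 0L) {
      tr$cuts_incomplete[li$row] <- TRUE
      next
    }
    pred <- if (!is.null(fit)) {
      as.numeric(stats::predict(fit, newdata = li, allow.new.levels = TRUE))
    } else {
      mean(donors$doy)
    }
    sy_obs <- obs[obs$site_year == li$site_year, "doy"]
    pred <- round(min(max(pred, min(sy_obs)), max(sy_obs)))
    imputed <- as.Date(pred - 1, origin = as.Date(sprintf("%d-01-01", li$year)))
    tr[[li$field]][li$row] <- imputed
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(row = li$row, field = li$field, imputed = imputed,
                 n_donors = nrow(donors), stringsAsFactors = FALSE)
  }
  ## keep last_cut consistent when a later cut was imputed past it
  fix <- !is.na(tr$cut2) & !is.na(tr$last_cut) & tr$cut2 > tr$last_cut
  tr$last_cut[fix] <- tr$cut2[fix]
  list(trials = tr,
       log = if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(row = integer(0), field = character(0),
                             imputed = as.Date(character(0)),
                             n_donors = integer(0)))
}

#' Select the estimation set and the reporting cultivar set
#'
#' All observations — including long-term control cultivars from outside
#' the reporting window — are retained for model estimation, because the
#' tested cultivar set turns over between years and the controls stabilise
#' the yield-level estimates.  Results (response profiles, max-diff, gap
#' flags) are reported only for modern cultivars: those tested within
#' `year_range` with at least `min_obs` usable observations.
#'
#' @param trials trial data frame.
#' @param year_range two-element integer vector, inclusive (default
#'   `c(2000, 2012)`).
#' @param min_obs minimum usable observations per reporting cultivar
#'   (default 20).
#' @param usable optional logical vector (length `nrow(trials)`) marking
#'   observations usable for the variable under analysis, e.g. those whose
#'   environment unit has a non-missing value; defaults to all usable.
#' @return A list with `estimation` (the full trial table), `reporting`
#'   (character vector of cultivar names) and `counts` (usable observation
#'   counts per in-window cultivar).
#' @export
select_reporting_set <- function(trials, year_range = c(2000L, 2012L),
                                 min_obs = 20L, usable = NULL) {
  if (is.null(usable)) usable <- rep(TRUE, nrow(trials))
  stopifnot(length(usable) == nrow(trials))
  in_window <- trials$harvest_year >= year_range[1] &
    trials$harvest_year <= year_range[2]
  modern <- unique(trials$cultivar[in_window])
  n_usable <- table(factor(trials$cultivar[usable & in_window], levels = modern))
  reporting <- names(n_usable)[n_usable >= min_obs]
  if (length(reporting) == 0L) {
    stop("empty reporting set: no cultivar tested in ", year_range[1], "-",
         year_range[2], " has >= ", min_obs, " usable observations")
  }
  list(estimation = trials,
       reporting = reporting,
       counts = as.data.frame(n_usable, responseName = "n_usable",
                              stringsAsFactors = FALSE))
}

#' Split environment units into observation-balanced tertiles
#'
#' Ranks environment units by the value of one agroclimatic variable and
#' cuts the ranking into three contiguous categories (low, moderate, high)
#' so that the trial *observations* are divided as equally as possible,
#' subject to two constraints: all observations of a unit share its label,
#' and units with exactly equal values share a label.  Equal thirds keep
#' the yield estimate of each category equally reliable.
#'
#' The partition is found by exhaustive search over the two break positions
#' between blocks of tied values, minimising the largest deviation of a
#' category's observation count from N/3; among optima the one with the
#' smallest breaks is chosen, so the result is deterministic.
#'
#' @param unit_values data frame with columns `unit_id`, `value` and
#'   optionally `n_obs` (observations carried by the unit, default 1).
#' @return A list with `labels` (data frame `unit_id`, `category` — a
#'   factor low/moderate/high), `breakpoints` (upper value edges of the low
#'   and moderate categories) and `counts` (observations per category).
#' @export
categorize_tertiles <- function(unit_values) {
  uv <- unit_values
  if (is.null(uv$n_obs)) uv$n_obs <- 1L
  uv <- uv[!is.na(uv$value), , drop = FALSE]
  if (nrow(uv) < 3L) stop("tertile categorization needs >= 3 units with values")
  if (length(unique(uv$value)) == 1L) {
    stop("degenerate distribution: all units share one value")
  }
  uv <- uv[order(uv$value, uv$unit_id), , drop = FALSE]

  ## blocks of tied values must stay together
  block_id <- cumsum(!duplicated(uv$value))
  b_obs <- as.numeric(tapply(uv$n_obs, block_id, sum))
  b_val <- as.numeric(tapply(uv$value, block_id, function(x) x[1]))
  B <- length(b_obs)
  if (B < 3L) stop("tertile categorization needs >= 3 distinct unit values")

  N <- sum(b_obs)
  csum <- cumsum(b_obs)
  best <- NULL
  best_dev <- Inf
  for (i in 1:(B - 2L)) {
    n1 <- csum[i]
    for (j in (i + 1L):(B - 1L)) {
      n2 <- csum[j] - csum[i]
      n3 <- N - csum[j]
      dev <- max(abs(c(n1, n2, n3) - N / 3))
      if (dev < best_dev - 1e-9) {
        best_dev <- dev
        best <- c(i, j)
      }
    }
  }
  labels <- cut(block_id, breaks = c(0, best[1], best[2], B),
                labels = c("low", "moderate", "high"))
  labels <- factor(as.character(labels), levels = c("low", "moderate", "high"))
  counts <- tapply(uv$n_obs, labels, sum)
  counts[is.na(counts)] <- 0
  list(labels = data.frame(unit_id = uv$unit_id, category = labels,
                           stringsAsFactors = FALSE),
       breakpoints = c(low_moderate = b_val[best[1]],
                       moderate_high = b_val[best[2]]),
       counts = counts)
}

#' Attach tertile category labels to trial observations
#'
#' @param trials trial data frame with `site_id`, `experiment_id`,
#'   `harvest_year` identifying each observation's environment unit.
#' @param unit_values data frame with `site_id`, `experiment_id`,
#'   `harvest_year` and the agroclimatic `value` of each unit; observations
#'   of units with a missing value receive `NA` labels.
#' @return A list with `observations` (the trial table plus `unit_id`,
#'   `unit_value` and `category` columns) and the `breakpoints` and
#'   `counts` of the underlying [categorize_tertiles()] call.
#' @export
categorize_observations <- function(trials, unit_values) {
  key <- function(d) paste(d$site_id, d$harvest_year, d$experiment_id, sep = ":")
  uv <- unit_values
  uv$unit_id <- key(uv)
  obs_per_unit <- table(factor(key(trials), levels = uv$unit_id))
  uv$n_obs <- as.integer(obs_per_unit[uv$unit_id])
  valued <- uv[!is.na(uv$value) & uv$n_obs > 0, , drop = FALSE]
  cat <- categorize_tertiles(valued[, c("unit_id", "value", "n_obs")])

  out <- trials
  out$unit_id <- key(trials)
  idx <- match(out$unit_id, uv$unit_id)
  out$unit_value <- uv$value[idx]
  lab_idx <- match(out$unit_id, cat$labels$unit_id)
  out$category <- factor(cat$labels$category[lab_idx],
                         levels = c("low", "moderate", "high"))
  list(observations = out, breakpoints = cat$breakpoints, counts = cat$counts)
}
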