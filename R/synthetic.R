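#' Configuration for the synthetic daily-weather generator
#'
#' Parameters of a simple stochastic weather model emulating a northern
#' (boreal) station: a sinusoidal annual temperature cycle plus AR(1)
#' day-to-day anomalies, daily min/max as offsets around the mean, and
#' mixed Bernoulli-gamma precipitation.  The defaults (annual mean 3 degC,
#' amplitude 14 degC) give winters with -10 degC frosts and -15 degC cold
#' stress days and springs with a 5-day warm spell, so nearly every
#' generated year segments into FH/WP/GP.
#'
#' @param mean annual mean temperature, degC.
#' @param amplitude seasonal half-range of the annual cycle, degC.
#' @param phase warmest day of year (default 200, mid July).
#' @param ar1 AR(1) coefficient of daily anomalies, in (-1, 1).
#' @param innovation_sd standard deviation of AR(1) innovations, degC.
#' @param tmin_offset,tmax_offset mean offsets of daily minimum/maximum
#'   from the daily mean, degC.
#' @param range_sd SD of the day-to-day jitter in those offsets, degC.
#' @param wet_prob probability a day is wet.
#' @param precip_shape,precip_scale gamma parameters of wet-day rainfall, mm.
#' @param seed integer seed; site/year sub-streams are derived from it.
#' @return A list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(mean = 3, amplitude = 14, phase = 200,
                               ar1 = 0.7, innovation_sd = 2.5,
                               tmin_offset = 4, tmax_offset = 4,
                               range_sd = 1.5,
                               wet_prob = 0.45,
                               precip_shape = 0.8, precip_scale = 4,
                               seed = 1L) {
  stopifnot(amplitude >= 0, wet_prob >= 0, wet_prob <= 1,
            ar1 > -1, ar1 < 1, innovation_sd >= 0,
            precip_shape > 0, precip_scale > 0)
  structure(list(mean = mean, amplitude = amplitude, phase = phase,
                 ar1 = ar1, innovation_sd = innovation_sd,
                 tmin_offset = tmin_offset, tmax_offset = tmax_offset,
                 range_sd = range_sd, wet_prob = wet_prob,
                 precip_shape = precip_shape, precip_scale = precip_scale,
                 seed = as.integer(seed)),
            class = "weather_gen_config")
}

## Deterministic sub-seed per site (and optional year) below 2^31, so
## sites can be generated independently yet reproducibly.
derive_subseed <- function(seed, site_id, year = 0L) {
  h <- sum(utf8ToInt(as.character(site_id)) * seq_along(utf8ToInt(as.character(site_id))))
  as.integer((as.numeric(seed) * 10007 + h * 131 + as.numeric(year)) %% 2147483647)
}

#' Generate a synthetic daily weather series
#'
#' Generates contiguous daily records from 1 January of the year before
#' the first requested season through 31 December of the last, so that
#' every season's fall-hardening window (starting 1 August of the
#' preceding year) is covered.
#'
#' @param config a [weather_gen_config()].
#' @param site_id site identifier.
#' @param years integer vector of season years the series must support.
#' @return Daily weather data frame (`site_id`, `date`, `tmean`, `tmin`,
#'   `tmax`, `precip`), byte-identical for identical inputs.
#' @export
generate_weather <- function(config, site_id, years) {
  stopifnot(inherits(config, "weather_gen_config"))
  from <- as.Date(sprintf("%d-01-01", min(years) - 1L))
  to <- as.Date(sprintf("%d-12-31", max(years)))
  dates <- seq(from, to, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))

  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(derive_subseed(config$seed, site_id))
    anom <- numeric(n)
    innov <- stats::rnorm(n, 0, config$innovation_sd)
    anom[1] <- innov[1] / sqrt(1 - config$ar1^2)
    for (i in 2:n) anom[i] <- config$ar1 * anom[i - 1] + innov[i]
    lo <- pmax(0, config$tmin_offset + stats::rnorm(n, 0, config$range_sd))
    hi <- pmax(0, config$tmax_offset + stats::rnorm(n, 0, config$range_sd))
    wet <- stats::rbinom(n, 1, config$wet_prob)
    amt <- stats::rgamma(n, shape = config$precip_shape,
                         scale = config$precip_scale)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    list(anom = anom, lo = lo, hi = hi, precip = wet * amt)
  })

  tmean <- config$mean +
    config$amplitude * cos(2 * pi * (doy - config$phase) / 365.25) +
    rng$anom
  data.frame(site_id = as.character(site_id), date = dates,
             tmean = tmean, tmin = tmean - rng$lo, tmax = tmean + rng$hi,
             precip = rng$precip, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic trial-yield generator
#'
#' Parameters of a forward simulation of the cultivar-by-category mixed
#' model over a trial network.  The defaults mirror the structure of the
#' northern forage variety trials the package targets: grand mean
#' 7000 kg DM/ha, a unit (site x year x experiment) random effect SD of
#' 1000 kg/ha that dominates the residual SD of 400 kg/ha, and two to
#' three cuts per season.
#'
#' Category effects are planted on the *true* tertile of a chosen
#' agroclimatic variable computed from the generated weather, so the whole
#' pipeline — segmentation, variable computation, categorization, model
#' fit — is exercised against known truth.
#'
#' @param n_sites,n_years,n_exps network size: sites, years, experiments
#'   per site-year.
#' @param n_cultivars cultivars of the simulated species.
#' @param species species label attached to the records.
#' @param mu grand mean annual DM yield, kg/ha.
#' @param cultivar_sd SD of cultivar main effects, kg/ha (effects are
#'   drawn once per dataset).
#' @param category_effects length-3 numeric (low, moderate, high), kg/ha.
#' @param interaction_range planted cultivar-response range, kg/ha: each
#'   cultivar i gets a response `r_i` evenly spaced over
#'   `[-range/2, +range/2]`, entering the yield as `r_i * x_j` with
#'   `x = (-0.5, 0, +0.5)` for low/moderate/high, so the high-minus-low
#'   responses span exactly `interaction_range`.  0 = no interaction.
#' @param interaction_matrix optional explicit cultivar x category effect
#'   matrix (rows = cultivars, columns = low/moderate/high); overrides
#'   `interaction_range`.
#' @param sigma_unit,sigma_eps unit and residual SDs, kg/ha.
#' @param variable agroclimatic variable whose tertiles carry the planted
#'   category effects (default `"GP_TSUM5"`).
#' @param first_year first harvest year (default 2005).
#' @param cut1_doy,cut2_doy,cut3_doy mean cut days of year.
#' @param cut_jitter_sd SD of per-unit cut-date jitter, days.
#' @param third_cut_prob probability a unit takes a third cut.
#' @param seed integer seed.
#' @return A list of class `trial_gen_config`.
#' @export
trial_gen_config <- function(n_sites = 5L, n_years = 3L, n_exps = 2L,
                             n_cultivars = 6L, species = "timothy",
                             mu = 7000, cultivar_sd = 300,
                             category_effects = c(low = -500, moderate = 0,
                                                  high = 500),
                             interaction_range = 0,
                             interaction_matrix = NULL,
                             sigma_unit = 1000, sigma_eps = 400,
                             variable = "GP_TSUM5",
                             first_year = 2005L,
                             cut1_doy = 170L, cut2_doy = 220L,
                             cut3_doy = 255L, cut_jitter_sd = 4,
                             third_cut_prob = 0.5,
                             seed = 1L) {
  stopifnot(sigma_unit >= 0, sigma_eps >= 0, cultivar_sd >= 0,
            length(category_effects) == 3L, interaction_range >= 0,
            n_sites >= 1, n_years >= 1, n_exps >= 1, n_cultivars >= 2)
  structure(as.list(environment()), class = "trial_gen_config")
}

#' Generate a synthetic variety-trial dataset with known truth
#'
#' Runs the cultivar-by-category model forward over a simulated trial
#' network: builds the environment units, segments each unit's season from
#' the supplied (or generated) weather, computes the configured
#' agroclimatic variable, assigns true tertile categories by unit, and
#' draws yields
#' `y = mu + cultivar_i + category_j + interaction_ij + u_unit + eps`.
#'
#' @param config a [trial_gen_config()].
#' @param weather optional daily weather data frame covering the network's
#'   sites and years; generated with default [weather_gen_config()] (same
#'   seed) when omitted.
#' @return A list with `trials` (observation table, one row per unit x
#'   cultivar), `units` (per-unit segmentation, variable value, true
#'   category), `weather`, and `truth` (every planted effect: cultivar
#'   effects, category effects, interaction matrix, unit effects, the
#'   response range and tertile breakpoints).
#' @export
generate_trials <- function(config, weather = NULL) {
  stopifnot(inherits(config, "trial_gen_config"))
  cfg <- config
  sites <- sprintf("S%02d", seq_len(cfg$n_sites))
  years <- seq(cfg$first_year, length.out = cfg$n_years)
  if (is.null(weather)) {
    wcfg <- weather_gen_config(seed = cfg$seed)
    weather <- do.call(rbind, lapply(sites, generate_weather,
                                     config = wcfg, years = years))
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(derive_subseed(cfg$seed, "trials"))

  ## environment units with jittered cut schedules
  units <- expand.grid(site_id = sites, harvest_year = years,
                       experiment_id = sprintf("E%d", seq_len(cfg$n_exps)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[order(units$site_id, units$harvest_year,
                       units$experiment_id), , drop = FALSE]
  n_u <- nrow(units)
  jit <- function(doy) round(doy + stats::rnorm(n_u, 0, cfg$cut_jitter_sd))
  y0 <- as.Date(sprintf("%d-01-01", units$harvest_year)) - 1
  units$cut1 <- y0 + jit(cfg$cut1_doy)
  units$cut2 <- y0 + pmax(jit(cfg$cut2_doy),
                          as.integer(units$cut1 - y0) + 14L)
  third <- stats::rbinom(n_u, 1, cfg$third_cut_prob) == 1
  cut3 <- y0 + pmax(jit(cfg$cut3_doy), as.integer(units$cut2 - y0) + 14L)
  units$last_cut <- as.Date(ifelse(third, cut3, units$cut2),
                            origin = "1970-01-01")

  ## segment each unit's season and compute the planted variable
  seasons <- data.frame(site_id = units$site_id,
                        season_year = units$harvest_year,
                        last_harvest = units$last_cut,
                        stringsAsFactors = FALSE)
  seg <- segment_seasons(weather, seasons)
  units <- cbind(units, seg[, c("fh_start", "fh_end", "wp_start", "wp_end",
                                "gp_start", "gp_end", "flags")])
  vals <- compute_all_variables(units, weather, ids = cfg$variable)
  units$value <- vals[[cfg$variable]]
  ok <- !is.na(units$value)
  if (sum(ok) < 3L) stop("fewer than 3 units segmented successfully; ",
                         "tertile structure impossible")
  units <- units[ok, , drop = FALSE]
  n_u <- nrow(units)
  units$unit_id <- paste(units$site_id, units$harvest_year,
                         units$experiment_id, sep = ":")

  ## true tertiles by unit rank on the variable
  rk <- rank(units$value, ties.method = "first")
  units$category <- factor(
    c("low", "moderate", "high")[ceiling(3 * rk / n_u)],
    levels = c("low", "moderate", "high"))

  ## planted effects
  cultivars <- sprintf("CV%02d", seq_len(cfg$n_cultivars))
  cult_eff <- stats::rnorm(cfg$n_cultivars, 0, cfg$cultivar_sd)
  cult_eff <- cult_eff - mean(cult_eff)
  names(cult_eff) <- cultivars
  cat_eff <- as.numeric(cfg$category_effects)
  names(cat_eff) <- c("low", "moderate", "high")
  if (!is.null(cfg$interaction_matrix)) {
    inter <- cfg$interaction_matrix
    stopifnot(nrow(inter) == cfg$n_cultivars, ncol(inter) == 3L)
  } else if (cfg$interaction_range > 0) {
    resp <- seq(-cfg$interaction_range / 2, cfg$interaction_range / 2,
                length.out = cfg$n_cultivars)
    inter <- outer(resp, c(-0.5, 0, 0.5))
  } else {
    inter <- matrix(0, cfg$n_cultivars, 3L)
  }
  dimnames(inter) <- list(cultivars, c("low", "moderate", "high"))
  u_eff <- stats::rnorm(n_u, 0, cfg$sigma_unit)
  names(u_eff) <- units$unit_id

  obs <- merge(units[, c("unit_id", "site_id", "experiment_id",
                         "harvest_year", "category", "cut1", "cut2",
                         "last_cut")],
               data.frame(cultivar = cultivars, stringsAsFactors = FALSE))
  obs <- obs[order(obs$unit_id, obs$cultivar), , drop = FALSE]
  ci <- match(obs$cultivar, cultivars)
  cj <- as.integer(obs$category)
  eps <- stats::rnorm(nrow(obs), 0, cfg$sigma_eps)
  obs$annual_dm_yield <- cfg$mu + cult_eff[ci] + cat_eff[cj] +
    inter[cbind(ci, cj)] + u_eff[obs$unit_id] + eps
  obs$species <- cfg$species
  obs$origin <- ifelse(ci %% 2 == 0, "foreign", "domestic")
  rownames(obs) <- NULL

  sorted <- sort(units$value)
  truth <- list(mu = cfg$mu, cultivar_effects = cult_eff,
                category_effects = cat_eff, interaction = inter,
                response_range = if (cfg$interaction_range > 0)
                  cfg$interaction_range else max(inter[, "high"] - inter[, "low"]) -
                  min(inter[, "high"] - inter[, "low"]),
                unit_effects = u_eff,
                sigma_unit = cfg$sigma_unit, sigma_eps = cfg$sigma_eps,
                variable = cfg$variable,
                categories = stats::setNames(units$category, units$unit_id))
  list(trials = obs, units = units, weather = weather, truth = truth)
}

#' Mask a fraction of cut dates
#'
#' Randomly blanks cut-date fields to emulate the sporadically missing
#' harvest dates of real trial archives (historically around 1%), keeping
#' the original values in the returned truth record for recovery tests.
#'
#' @param trials trial data frame with `cut1`, `cut2`, `last_cut`.
#' @param fraction fraction of date fields to mask, in `[0, 1)`.
#' @param seed integer seed.
#' @return A list with `trials` (dates masked) and `masked` (data frame
#'   `row`, `field`, `true_date`).
#' @export
mask_cut_dates <- function(trials, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) {
    return(list(trials = trials,
                masked = data.frame(row = integer(0), field = character(0),
                                    true_date = as.Date(character(0)))))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  fields <- c("cut1", "cut2", "last_cut")
  cand <- do.call(rbind, lapply(fields, function(f) {
    rows <- which(!is.na(trials[[f]]))
    if (length(rows)) data.frame(row = rows, field = f,
                                 stringsAsFactors = FALSE)
  }))
  n_mask <- round(fraction * nrow(cand))
  if (n_mask == 0L) {
    return(list(trials = trials,
                masked = data.frame(row = integer(0), field = character(0),
                                    true_date = as.Date(character(0)))))
  }
  pick <- cand[sample.int(nrow(cand), n_mask), , drop = FALSE]
  pick$true_date <- as.Date(vapply(seq_len(nrow(pick)), function(i) {
    as.character(trials[[pick$field[i]]][pick$row[i]])
  }, character(1)))
  out <- trials
  for (i in seq_len(nrow(pick))) {
    out[[pick$field[i]]][pick$row[i]] <- as.Date(NA)
  }
  rownames(pick) <- NULL
  list(trials = out, masked = pick)
}
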