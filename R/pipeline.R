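#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: either paths to weather and
#' trial CSVs or generator configurations, the variable subset, the
#' gap-rule thresholds, the degrees-of-freedom method, the reporting
#' window and minimum-observation rule, the output directory and the seed.
#'
#' @param weather_csv,trials_csv input file paths (mutually exclusive with
#'   the generator configs).
#' @param weather_config,trial_config generator configurations
#'   ([weather_gen_config()], [trial_gen_config()]) for a simulated run.
#' @param variables agroclimatic variable ids to analyse (default: all 14).
#' @param alpha_e,alpha_gxe gap-rule significance thresholds.
#' @param df_method `"satterthwaite"` or `"residual"`.
#' @param year_range reporting window, inclusive.
#' @param min_obs minimum usable observations per reporting cultivar.
#' @param outdir output directory (created if needed).
#' @param seed integer seed (generator runs).
#' @param strict abort on input-validation violations instead of warning.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(weather_csv = NULL, trials_csv = NULL,
                            weather_config = NULL, trial_config = NULL,
                            variables = acv_registry()$id,
                            alpha_e = 0.05, alpha_gxe = 0.05,
                            df_method = c("satterthwaite", "residual"),
                            year_range = c(2000L, 2012L), min_obs = 20L,
                            outdir = tempfile("respdiv_run_"),
                            seed = 1L, strict = FALSE) {
  df_method <- match.arg(df_method)
  stopifnot(alpha_e > 0, alpha_e < 1, alpha_gxe > 0, alpha_gxe < 1)
  from_files <- !is.null(weather_csv) && !is.null(trials_csv)
  from_sim <- !is.null(trial_config)
  if (!from_files && !from_sim) {
    stop("supply either weather_csv + trials_csv or a trial_config")
  }
  if (from_files) {
    for (p in c(weather_csv, trials_csv)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
  }
  stopifnot(all(variables %in% acv_registry()$id))
  structure(list(weather_csv = weather_csv, trials_csv = trials_csv,
                 weather_config = weather_config, trial_config = trial_config,
                 variables = variables, alpha_e = alpha_e,
                 alpha_gxe = alpha_gxe, df_method = df_method,
                 year_range = year_range, min_obs = min_obs,
                 outdir = outdir, seed = as.integer(seed), strict = strict),
            class = "pipeline_config")
}

#' Demonstration configuration with a planted adaptive-capacity gap
#'
#' A small simulated run whose ground truth contains a gap: a strong
#' category (environment) effect on yield with zero planted
#' cultivar-by-category interaction, so the analysed variable must come
#' out with significant E, non-significant G x E and `gap = TRUE`.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(outdir = tempfile("respdiv_demo_"),
                                 seed = 1L) {
  tc <- trial_gen_config(n_sites = 5L, n_years = 3L, n_exps = 2L,
                         n_cultivars = 6L,
                         category_effects = c(low = -900, moderate = 0,
                                              high = 900),
                         interaction_range = 0,
                         first_year = 2005L,
                         seed = seed)
  pipeline_config(trial_config = tc, variables = "GP_TSUM5",
                  year_range = c(2000L, 2012L), min_obs = 20L,
                  outdir = outdir, seed = seed)
}

#' Validate weather and trial inputs
#'
#' Reports duplicate site-days, non-contiguous weather dates, temperature
#' ordering violations (tmin > tmean or tmean > tmax), negative
#' precipitation, cut-date ordering violations, unknown species and
#' non-positive yields.  Non-fatal by default; in strict mode any
#' violation aborts.
#'
#' @param weather daily weather data frame.
#' @param trials trial data frame.
#' @param strict abort on violations.
#' @return Data frame with columns `check`, `where`, `message`; zero rows
#'   when the inputs are clean.
#' @export
validate_inputs <- function(weather, trials, strict = FALSE) {
  issues <- list()
  add <- function(check, where, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      check = check, where = where, message = message,
      stringsAsFactors = FALSE)
  }

  key <- paste(weather$site_id, weather$date)
  dup <- unique(key[duplicated(key)])
  for (d in utils::head(dup, 10L)) add("duplicate_site_day", d, "duplicate weather record")

  for (s in unique(weather$site_id)) {
    dates <- sort(weather$date[weather$site_id == s])
    gaps <- which(diff(dates) > 1)
    for (g in utils::head(gaps, 10L)) {
      add("non_contiguous_dates", s,
          sprintf("gap between %s and %s", dates[g], dates[g + 1]))
    }
  }

  bad_t <- which(weather$tmin > weather$tmean | weather$tmean > weather$tmax)
  for (i in utils::head(bad_t, 10L)) {
    add("temperature_ordering", paste(weather$site_id[i], weather$date[i]),
        "tmin <= tmean <= tmax violated")
  }
  bad_p <- which(weather$precip < 0)
  for (i in utils::head(bad_p, 10L)) {
    add("negative_precip", paste(weather$site_id[i], weather$date[i]),
        "negative precipitation")
  }

  bad_cut <- which(!is.na(trials$cut1) & !is.na(trials$cut2) &
                     trials$cut2 <= trials$cut1)
  for (i in bad_cut) add("cut_order", paste0("row ", i), "cut2 not after cut1")
  bad_last <- which(!is.na(trials$cut2) & !is.na(trials$last_cut) &
                      trials$last_cut < trials$cut2)
  for (i in bad_last) add("cut_order", paste0("row ", i), "last_cut before cut2")

  known <- c("timothy", "meadow_fescue", "tall_fescue", "festulolium",
             "red_clover")
  bad_sp <- which(!trials$species %in% known)
  for (i in utils::head(bad_sp, 10L)) {
    add("unknown_species", paste0("row ", i), trials$species[i])
  }
  bad_y <- which(!is.finite(trials$annual_dm_yield) | trials$annual_dm_yield <= 0)
  for (i in utils::head(bad_y, 10L)) {
    add("yield_range", paste0("row ", i), "non-positive or missing yield")
  }

  report <- if (length(issues)) do.call(rbind, issues) else
    data.frame(check = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
  if (strict && nrow(report) > 0L) {
    stop("input validation failed with ", nrow(report), " issue(s); first: ",
         report$check[1], " at ", report$where[1])
  }
  report
}

#' Run the full response-diversity pipeline
#'
#' Executes the stage sequence segment -> variables -> categorize -> fit
#' -> assess and writes five CSVs (`segmentation.csv`, `variables.csv`,
#' `categories.csv`, `results.csv`, `profiles.csv`) plus a machine-readable
#' `manifest.json` (configuration echo, seed, stage counts) to the
#' configured output directory.  Reruns with an identical configuration
#' and seed reproduce identical result files.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory `segmentation`,
#'   `variables`, `results` and `profiles` tables and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  ## stage 0: inputs
  if (!is.null(config$trial_config)) {
    gen <- generate_trials(config$trial_config)
    weather <- gen$weather
    trials <- gen$trials
  } else {
    weather <- read_weather_csv(config$weather_csv)
    trials <- read_trials_csv(config$trials_csv)
  }
  report <- validate_inputs(weather, trials, strict = config$strict)
  if (nrow(report) > 0L) {
    warning("input validation reported ", nrow(report), " issue(s)")
  }

  imp <- impute_missing_cut_dates(trials)
  trials <- imp$trials

  ## stage 1: segmentation, one unit per site x year x experiment; the GP
  ## ends with the unit's own last harvest, so cut schedules are unit-level
  ukey <- paste(trials$site_id, trials$harvest_year, trials$experiment_id,
                sep = ":")
  usable_obs <- !trials$cuts_incomplete
  first <- !duplicated(ukey) & usable_obs
  units <- data.frame(site_id = trials$site_id[first],
                      experiment_id = trials$experiment_id[first],
                      harvest_year = trials$harvest_year[first],
                      cut1 = trials$cut1[first], cut2 = trials$cut2[first],
                      last_cut = trials$last_cut[first],
                      stringsAsFactors = FALSE)
  seg <- segment_seasons(weather,
                         data.frame(site_id = units$site_id,
                                    season_year = units$harvest_year,
                                    last_harvest = units$last_cut,
                                    stringsAsFactors = FALSE))
  write_segmentation_csv(seg, file.path(config$outdir, "segmentation.csv"))
  units <- cbind(units, seg[, c("fh_start", "fh_end", "wp_start", "wp_end",
                                "gp_start", "gp_end", "flags")])

  ## stage 2: agroclimatic variables
  vars <- compute_all_variables(units, weather, ids = config$variables)
  write_variables_csv(vars, file.path(config$outdir, "variables.csv"))

  ## stages 3-5 per species x variable
  species_list <- sort(unique(trials$species))
  results <- list()
  profiles <- list()
  categories_out <- list()
  for (sp in species_list) {
    sp_obs <- trials[trials$species == sp & usable_obs, , drop = FALSE]
    fits <- stats::setNames(vector("list", length(config$variables)),
                            config$variables)
    reporting_by_var <- list()
    for (v in config$variables) {
      uv <- data.frame(site_id = vars$site_id,
                       experiment_id = vars$experiment_id,
                       harvest_year = vars$harvest_year,
                       value = vars[[v]], stringsAsFactors = FALSE)
      catres <- tryCatch(categorize_observations(sp_obs, uv),
                         error = function(e) NULL)
      if (is.null(catres)) next
      obs <- catres$observations
      usable <- !is.na(obs$category)
      rep_set <- tryCatch(
        select_reporting_set(obs, config$year_range, config$min_obs, usable),
        error = function(e) NULL)
      if (is.null(rep_set)) next
      categories_out[[paste(sp, v)]] <- data.frame(
        obs[, c("site_id", "experiment_id", "harvest_year", "species",
                "cultivar", "annual_dm_yield", "unit_value", "category")],
        variable_id = v,
        breakpoint_low_moderate = catres$breakpoints[["low_moderate"]],
        breakpoint_moderate_high = catres$breakpoints[["moderate_high"]],
        stringsAsFactors = FALSE)
      fit <- tryCatch(
        fit_gxe_model(obs[usable, , drop = FALSE],
                      df_method = config$df_method),
        error = function(e) NULL)
      fits[[v]] <- fit
      if (!is.null(fit)) reporting_by_var[[v]] <- rep_set$reporting
    }
    summ <- summarize_species(fits, sp,
                              alpha_e = config$alpha_e,
                              alpha_gxe = config$alpha_gxe)
    if (!is.null(summ$table)) {
      ## max diff and profiles restricted to each variable's reporting set
      for (v in names(reporting_by_var)) {
        f <- fits[[v]]
        md <- max_diff(f, reporting_by_var[[v]])
        summ$table$max_diff[summ$table$variable_id == v] <- md$value
        summ$table$max_diff_sign[summ$table$variable_id == v] <- md$sign
        in_win <- sp_obs$harvest_year >= config$year_range[1] &
          sp_obs$harvest_year <= config$year_range[2]
        denom <- mean(sp_obs$annual_dm_yield[
          in_win & sp_obs$cultivar %in% reporting_by_var[[v]]])
        prof <- response_profile(f, reporting_by_var[[v]], denom)
        prof <- data.frame(species = sp, variable_id = v, prof,
                           stringsAsFactors = FALSE)
        profiles[[paste(sp, v)]] <- prof
      }
      results[[sp]] <- summ$table
    }
  }

  results_df <- if (length(results)) do.call(rbind, results) else NULL
  profiles_df <- if (length(profiles)) do.call(rbind, profiles) else NULL
  categories_df <- if (length(categories_out)) do.call(rbind, categories_out) else NULL
  if (!is.null(results_df)) rownames(results_df) <- NULL
  if (!is.null(profiles_df)) rownames(profiles_df) <- NULL
  if (!is.null(categories_df)) rownames(categories_df) <- NULL

  utils::write.csv(categories_df, file.path(config$outdir, "categories.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(results_df, file.path(config$outdir, "results.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(profiles_df, file.path(config$outdir, "profiles.csv"),
                   row.names = FALSE, na = "")

  manifest <- list(
    seed = config$seed,
    df_method = config$df_method,
    alpha_e = config$alpha_e, alpha_gxe = config$alpha_gxe,
    year_range = config$year_range, min_obs = config$min_obs,
    variables = config$variables,
    n_weather_rows = nrow(weather),
    n_trial_obs = nrow(trials),
    n_obs_excluded_cuts_incomplete = sum(trials$cuts_incomplete),
    n_imputed_cut_dates = nrow(imp$log),
    n_units = nrow(units),
    n_validation_issues = nrow(report),
    n_results = if (is.null(results_df)) 0L else nrow(results_df),
    n_gaps = if (is.null(results_df)) 0L else sum(results_df$gap, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(segmentation = seg, variables = vars,
                 categories = categories_df, results = results_df,
                 profiles = profiles_df, manifest = manifest))
}
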