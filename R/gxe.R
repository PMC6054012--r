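#' Fit the cultivar-by-environment-category mixed model
#'
#' Fits, by restricted maximum likelihood, the model
#'
#' \deqn{y_{ij} = \mu + G_i + E_j + (G \times E)_{ij} + u_{unit(j)} + \varepsilon}
#'
#' where \eqn{G_i} is the cultivar, \eqn{E_j} the low/moderate/high
#' environment category of an agroclimatic variable, \eqn{(G\times E)_{ij}}
#' their interaction (all fixed), and \eqn{u} a random intercept for each
#' experimental site x year x trial unit, nested in category (every unit
#' carries exactly one label).  Marginal (Type-III) F tests are reported
#' for G, E and G x E; cell means are least-squares means.
#'
#' Degrees of freedom for the F tests use the Satterthwaite approximation
#' by default; `df_method = "residual"` substitutes the residual
#' degrees of freedom `n - rank(X)` as a conservative fallback.
#'
#' @param data data frame with columns `annual_dm_yield`, `cultivar`,
#'   `category` (factor with levels low/moderate/high) and `unit_id`.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @param lsmeans compute least-squares means (default `TRUE`; can be
#'   switched off in large simulation loops that only need the F tests).
#' @return An object of class `gxe_fit`: a list with the fitted `model`,
#'   the `anova` table, named scalars `F_G`, `p_G`, `F_E`, `p_E`, `F_GxE`,
#'   `p_GxE`, variance components `sigma2_unit`, `sigma2_resid`, a
#'   `lsmeans` data frame (`cultivar`, `category`, `lsmean`, `se`),
#'   `converged`, `singular`, `empty_cells`, `n_obs`, `n_cultivars` and
#'   `df_method`.
#' @export
fit_gxe_model <- function(data, df_method = c("satterthwaite", "residual"),
                          lsmeans = TRUE) {
  df_method <- match.arg(df_method)
  d <- data
  d$cultivar <- factor(d$cultivar)
  d$category <- factor(d$category, levels = c("low", "moderate", "high"))
  d <- d[!is.na(d$category) & !is.na(d$annual_dm_yield), , drop = FALSE]
  d$cultivar <- droplevels(d$cultivar)
  d$category <- droplevels(d$category)

  if (nlevels(d$category) < 3L) {
    stop("all three environment categories must be present (got ",
         nlevels(d$category), ")")
  }
  if (nlevels(d$cultivar) < 2L) stop("need at least 2 cultivars")
  units_per_cat <- tapply(d$unit_id, d$category,
                          function(x) length(unique(x)))
  if (any(units_per_cat < 2L)) {
    stop("need >= 2 environment units per category")
  }

  cell <- table(d$cultivar, d$category)
  empty <- which(cell == 0, arr.ind = TRUE)
  empty_cells <- if (nrow(empty)) {
    data.frame(cultivar = rownames(cell)[empty[, 1]],
               category = colnames(cell)[empty[, 2]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(cultivar = character(0), category = character(0))
  }
  if (nrow(empty_cells)) {
    warning(nrow(empty_cells),
            " cultivar x category cell(s) have no observations; ",
            "tests computed on the estimable subspace")
  }

  fit <- lmerTest::lmer(
    annual_dm_yield ~ cultivar * category + (1 | unit_id),
    data = d, REML = TRUE,
    contrasts = list(cultivar = "contr.sum", category = "contr.sum"),
    control = lme4::lmerControl(
      calc.derivs = FALSE,
      optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8, maxeval = 2e4),
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))

  conv <- (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0) &&
    length(fit@optinfo$conv$lme4$messages) == 0L
  singular <- lme4::isSingular(fit, tol = 1e-4)

  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  pick <- function(term) an[rownames(an) == term, , drop = FALSE]
  rG <- pick("cultivar"); rE <- pick("category"); rI <- pick("cultivar:category")
  getF <- function(r) if (nrow(r)) r$`F value` else NA_real_
  getp <- function(r) if (nrow(r)) r$`Pr(>F)` else NA_real_
  getdf <- function(r) if (nrow(r)) r$NumDF else NA_real_

  if (df_method == "residual") {
    rdf <- stats::nobs(fit) - length(lme4::fixef(fit))
    getp <- function(r) {
      if (!nrow(r)) return(NA_real_)
      stats::pf(r$`F value`, r$NumDF, rdf, lower.tail = FALSE)
    }
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_unit <- vc$vcov[vc$grp == "unit_id"]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]

  lsm <- NULL
  if (lsmeans) {
    em <- suppressMessages(
      emmeans::emmeans(fit, ~ cultivar:category, lmer.df = "asymptotic"))
    es <- as.data.frame(em)
    lsm <- data.frame(cultivar = as.character(es$cultivar),
                      category = as.character(es$category),
                      lsmean = es$emmean, se = es$SE,
                      stringsAsFactors = FALSE)
  }

  structure(list(model = fit, anova = an,
                 F_G = getF(rG), p_G = getp(rG), df_G = getdf(rG),
                 F_E = getF(rE), p_E = getp(rE), df_E = getdf(rE),
                 F_GxE = getF(rI), p_GxE = getp(rI), df_GxE = getdf(rI),
                 sigma2_unit = sigma2_unit, sigma2_resid = sigma2_resid,
                 lsmeans = lsm, converged = conv, singular = singular,
                 empty_cells = empty_cells,
                 n_obs = nrow(d), n_cultivars = nlevels(d$cultivar),
                 df_method = df_method),
            class = "gxe_fit")
}

#' @exportS3Method base::print
print.gxe_fit <- function(x, ...) {
  cat("Cultivar x environment-category mixed model (REML)\n")
  cat(sprintf("  %d observations, %d cultivars, df method: %s\n",
              x$n_obs, x$n_cultivars, x$df_method))
  cat(sprintf("  sigma2(unit) = %.1f, sigma2(resid) = %.1f\n",
              x$sigma2_unit, x$sigma2_resid))
  cat(sprintf("  G:    F = %8.3f  p = %.4g %s\n", x$F_G, x$p_G,
              significance_stars(x$p_G)))
  cat(sprintf("  E:    F = %8.3f  p = %.4g %s\n", x$F_E, x$p_E,
              significance_stars(x$p_E)))
  cat(sprintf("  GxE:  F = %8.3f  p = %.4g %s\n", x$F_GxE, x$p_GxE,
              significance_stars(x$p_GxE)))
  invisible(x)
}

#' Significance stars
#'
#' Star scheme used in the result tables: `*` p <= 0.10 (tendency),
#' `**` p <= 0.05, `***` p <= 0.01, `****` p <= 0.001; empty otherwise.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  out <- rep("", length(p))
  out[!is.na(p) & p <= 0.10] <- "*"
  out[!is.na(p) & p <= 0.05] <- "**"
  out[!is.na(p) & p <= 0.01] <- "***"
  out[!is.na(p) & p <= 0.001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Response profile as percent of the species average yield
#'
#' Expresses each reporting cultivar's least-squares mean in every
#' environment category as a percentage of the species' average annual
#' yield over the reporting cultivars, the scale used in the per-species
#' response figures (100\% = the species average).
#'
#' @param fit a [fit_gxe_model()] result with LS-means.
#' @param reporting character vector of reporting cultivar names.
#' @param species_mean average annual DM yield (kg/ha) of the reporting
#'   cultivars' observations; must be positive.
#' @return Data frame `cultivar`, `category`, `lsmean`, `percent_of_average`.
#' @export
response_profile <- function(fit, reporting, species_mean) {
  if (is.null(fit$lsmeans)) stop("fit has no LS-means (lsmeans = FALSE?)")
  if (!is.finite(species_mean) || species_mean <= 0) {
    stop("species mean yield must be positive")
  }
  lsm <- fit$lsmeans[fit$lsmeans$cultivar %in% reporting, , drop = FALSE]
  lsm$percent_of_average <- 100 * lsm$lsmean / species_mean
  rownames(lsm) <- NULL
  lsm
}

#' Max-diff: the spread of cultivar responses to an agroclimatic variable
#'
#' Each cultivar's response is its least-squares-mean yield in the high
#' category minus that in the low category.  The max-diff statistic is the
#' difference between the largest and the smallest cultivar response
#' (always a non-negative magnitude); its reported sign is the sign of the
#' species-level high-minus-low contrast, so a negative max diff marks a
#' variable whose high category depresses yields overall.
#'
#' @param fit a [fit_gxe_model()] result with LS-means.
#' @param reporting cultivars over which the spread is taken (default: all
#'   cultivars in the fit).
#' @return A list with `value` (signed, kg/ha), `magnitude`, `sign` (+1 or
#'   -1), and `responses` (per-cultivar high-minus-low contrasts).  `value`
#'   is `NA` when fewer than two cultivars have both cells estimable.
#' @export
max_diff <- function(fit, reporting = NULL) {
  if (is.null(fit$lsmeans)) stop("fit has no LS-means (lsmeans = FALSE?)")
  lsm <- fit$lsmeans
  if (!is.null(reporting)) lsm <- lsm[lsm$cultivar %in% reporting, ]
  hi <- lsm[lsm$category == "high", c("cultivar", "lsmean")]
  lo <- lsm[lsm$category == "low", c("cultivar", "lsmean")]
  m <- merge(hi, lo, by = "cultivar", suffixes = c("_high", "_low"))
  m <- m[is.finite(m$lsmean_high) & is.finite(m$lsmean_low), , drop = FALSE]
  m$response <- m$lsmean_high - m$lsmean_low
  if (nrow(m) < 2L) {
    return(list(value = NA_real_, magnitude = NA_real_, sign = NA_real_,
                responses = m))
  }
  magnitude <- max(m$response) - min(m$response)
  species_contrast <- mean(m$lsmean_high) - mean(m$lsmean_low)
  sgn <- if (species_contrast < 0) -1 else 1
  list(value = sgn * magnitude, magnitude = magnitude, sign = sgn,
       responses = m[, c("cultivar", "response")])
}

#' Classify an adaptive-capacity gap
#'
#' A gap in adaptive capacity is declared for an agroclimatic variable
#' when the species as a whole responds to it (significant environment
#' effect E) but the cultivars do not differ in their responses
#' (non-significant G x E): every cultivar is hit alike, so the cultivar
#' pool offers no buffering against that factor.
#'
#' @param p_e p-value of the environment (category) main effect.
#' @param p_gxe p-value of the cultivar-by-category interaction.
#' @param alpha_e,alpha_gxe significance thresholds (default 0.05 each).
#' @return A list with `gap` (logical, `NA` if a p-value is missing) and a
#'   human-readable `rationale`.
#' @export
classify_gap <- function(p_e, p_gxe, alpha_e = 0.05, alpha_gxe = 0.05) {
  if (is.na(p_e) || is.na(p_gxe)) {
    return(list(gap = NA,
                rationale = "undefined: missing p-value(s)"))
  }
  gap <- (p_e <= alpha_e) && (p_gxe > alpha_gxe)
  list(gap = gap,
       rationale = sprintf(
         "p_E = %.4g (alpha_E = %g, %s), p_GxE = %.4g (alpha_GxE = %g, %s) => %s",
         p_e, alpha_e, if (p_e <= alpha_e) "significant" else "ns",
         p_gxe, alpha_gxe, if (p_gxe <= alpha_gxe) "significant" else "ns",
         if (gap) "gap in adaptive capacity" else "no gap"))
}

#' Summarise all agroclimatic variables for one species
#'
#' Collects the fits of one species across agroclimatic variables into a
#' results table (max diff with significance stars for G x E and E, gap
#' flag) plus the count of variables with significant response diversity
#' (p_GxE <= `alpha_gxe`).
#'
#' @param fits named list of [fit_gxe_model()] results (names = variable
#'   ids); elements may be `NULL` for failed fits.
#' @param species species name carried into the table.
#' @param reporting reporting cultivar set for [max_diff()].
#' @param alpha_e,alpha_gxe gap-rule thresholds.
#' @return A list with `table` (one row per attempted variable),
#'   `n_sig_gxe` and `failed` (ids of variables without a fit).
#' @export
summarize_species <- function(fits, species, reporting = NULL,
                              alpha_e = 0.05, alpha_gxe = 0.05) {
  ids <- names(fits)
  rows <- lapply(ids, function(id) {
    f <- fits[[id]]
    if (is.null(f)) return(NULL)
    md <- if (!is.null(f$lsmeans)) max_diff(f, reporting)
          else list(value = NA_real_, sign = NA_real_)
    gp <- classify_gap(f$p_E, f$p_GxE, alpha_e, alpha_gxe)
    data.frame(species = species, variable_id = id,
               n_obs = f$n_obs, n_cultivars = f$n_cultivars,
               sigma2_unit = f$sigma2_unit, sigma2_resid = f$sigma2_resid,
               F_G = f$F_G, p_G = f$p_G,
               F_E = f$F_E, p_E = f$p_E,
               F_GxE = f$F_GxE, p_GxE = f$p_GxE,
               stars_E = significance_stars(f$p_E),
               stars_GxE = significance_stars(f$p_GxE),
               max_diff = md$value,
               max_diff_sign = md$sign,
               gap = gp$gap,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failed <- ids[vapply(fits, is.null, logical(1))]
  n_sig <- if (is.null(tab)) 0L else sum(tab$p_GxE <= alpha_gxe, na.rm = TRUE)
  list(table = tab, n_sig_gxe = n_sig, failed = failed)
}

#' Reported response-diversity summary of the Finnish forage trials
#'
#' Transcription of the published per-species summary of the Finnish
#' official variety-trial analysis this package's methods follow: for each
#' of five forage species (timothy, meadow fescue, festulolium, tall
#' fescue, red clover) and 14 agroclimatic variables, the reported max-diff
#' (kg DM/ha), the G x E p-value (printed numerically when not significant,
#' as stars when significant) and the environment-effect significance.
#' Used to verify the gap-classification logic against published results;
#' the underlying trial records themselves are not public.
#'
#' @return Data frame with columns `variable_id`, `species`, `max_diff`,
#'   `p_gxe` (`NA` when only stars were printed), `stars_gxe` (`NA` when a
#'   numeric p was printed), `p_e`, `stars_e`.
#' @export
reported_gxe_table <- function() {
  path <- system.file("extdata", "reported_gxe_summary.csv",
                      package = "respdiv", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(variable_id = "character",
                                 species = "character",
                                 max_diff = "numeric",
                                 p_gxe = "numeric", stars_gxe = "character",
                                 p_e = "numeric", stars_e = "character"))
}

#' Significance at a threshold from a printed p-value or star code
#'
#' Published tables often print an exact p-value only when an effect is
#' not significant and a star code otherwise.  This helper decides
#' significance at `alpha` from whichever was printed: a numeric p-value
#' when available, else the star code (`**` and beyond means p <= 0.05,
#' `*` alone is the 0.10 tendency level).
#'
#' @param p numeric p-value or `NA`.
#' @param stars star string or `NA`.
#' @param alpha significance threshold (0.05 or 0.10).
#' @return Logical vector.
#' @export
printed_significant <- function(p, stars, alpha = 0.05) {
  star_alpha <- c("*" = 0.10, "**" = 0.05, "***" = 0.01, "****" = 0.001)
  n <- max(length(p), length(stars))
  p <- rep_len(p, n); stars <- rep_len(stars, n)
  out <- logical(n)
  for (i in seq_len(n)) {
    out[i] <- if (!is.na(p[i])) {
      p[i] <= alpha
    } else if (!is.na(stars[i]) && nzchar(stars[i])) {
      star_alpha[[stars[i]]] <= alpha
    } else {
      FALSE
    }
  }
  out
}

#' Gap assessment over a results table
#'
#' Applies the gap rule (significant E, non-significant G x E at the given
#' thresholds) row-wise to a results table that carries either numeric
#' p-values (`p_e`, `p_gxe`) or printed star codes (`stars_e`,
#' `stars_gxe`), as in [reported_gxe_table()].
#'
#' @param results data frame with columns `p_e`/`stars_e` and
#'   `p_gxe`/`stars_gxe` (missing columns treated as all-`NA`).
#' @param alpha_e,alpha_gxe thresholds (default 0.05).
#' @return The input with logical columns `sig_e`, `sig_gxe`, `gap` added.
#' @export
gap_assessment <- function(results, alpha_e = 0.05, alpha_gxe = 0.05) {
  g <- function(col) if (col %in% names(results)) results[[col]] else NA
  sig_e <- printed_significant(g("p_e"), g("stars_e"), alpha_e)
  sig_gxe <- printed_significant(g("p_gxe"), g("stars_gxe"), alpha_gxe)
  results$sig_e <- sig_e
  results$sig_gxe <- sig_gxe
  results$gap <- sig_e & !sig_gxe
  results
}
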