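test_that("mixed-model F statistics match the split-plot ANOVA oracle on balanced data", {
  d <- simulate_gxe_design(seed = 101, response_range = 800)
  fit <- fit_gxe_model(d)
  ## classic balanced split-plot ANOVA: category tested against units,
  ## cultivar and interaction against the within-unit residual
  oa <- summary(stats::aov(annual_dm_yield ~ cultivar * category +
                             Error(factor(unit_id)), data = d))
  between <- oa[["Error: factor(unit_id)"]][[1]]
  within <- oa[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  F_E <- between["category", "Mean Sq"] / between["Residuals", "Mean Sq"]
  F_G <- within["cultivar", "Mean Sq"] / within["Residuals", "Mean Sq"]
  F_GxE <- within["cultivar:category", "Mean Sq"] /
    within["Residuals", "Mean Sq"]
  expect_equal(fit$F_E, F_E, tolerance = 1e-3)
  expect_equal(fit$F_G, F_G, tolerance = 1e-3)
  expect_equal(fit$F_GxE, F_GxE, tolerance = 1e-3)
})

test_that("with zero unit variance the fit collapses to the fixed-effects ANOVA", {
  ## balanced data, no unit effect planted: when the REML estimate of the
  ## unit component is zero, F statistics and LS-means must equal the
  ## two-way fixed-effects analysis exactly
  d <- simulate_gxe_design(seed = 2, response_range = 0, sigma_unit = 0)
  fit <- fit_gxe_model(d)
  expect_equal(fit$sigma2_unit, 0, tolerance = 1e-6)
  lmfit <- stats::lm(annual_dm_yield ~ cultivar * category, data = d,
                     contrasts = list(cultivar = "contr.sum",
                                      category = "contr.sum"))
  an <- stats::anova(lmfit)  # balanced: sequential = marginal
  expect_equal(fit$F_G, an["cultivar", "F value"], tolerance = 1e-3)
  expect_equal(fit$F_E, an["category", "F value"], tolerance = 1e-3)
  expect_equal(fit$F_GxE, an["cultivar:category", "F value"], tolerance = 1e-3)
  ## LS-means reproduce raw cell means on balanced data
  cm <- aggregate(annual_dm_yield ~ cultivar + category, d, mean)
  m <- merge(fit$lsmeans, cm)
  expect_equal(m$lsmean, m$annual_dm_yield, tolerance = 1e-6)
})

test_that("adding a constant shifts LS-means but leaves tests untouched", {
  d <- simulate_gxe_design(seed = 55, response_range = 600)
  f1 <- fit_gxe_model(d)
  d2 <- d
  d2$annual_dm_yield <- d2$annual_dm_yield + 1000
  f2 <- fit_gxe_model(d2)
  expect_equal(f1$F_G, f2$F_G, tolerance = 1e-6)
  expect_equal(f1$F_E, f2$F_E, tolerance = 1e-6)
  expect_equal(f1$F_GxE, f2$F_GxE, tolerance = 1e-6)
  expect_equal(f1$p_GxE, f2$p_GxE, tolerance = 1e-6)
  expect_equal(f2$lsmeans$lsmean, f1$lsmeans$lsmean + 1000, tolerance = 1e-6)
})

test_that("null interaction p-values are consistent with a uniform distribution", {
  p <- vapply(1:300, function(s) {
    fit_gxe_model(simulate_gxe_design(seed = 10000 + s), lsmeans = FALSE)$p_GxE
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("preconditions on categories, cultivars and units are enforced", {
  d <- simulate_gxe_design(seed = 3)
  expect_error(fit_gxe_model(d[d$category != "high", ]), "three environment categories")
  expect_error(fit_gxe_model(d[d$cultivar == "CV01", ]), "2 cultivars")
  ## an empty cultivar x category cell triggers a warning, not a failure
  d2 <- d[!(d$cultivar == "CV01" & d$category == "high"), ]
  expect_warning(fit_gxe_model(d2), "cell")
})

test_that("significance stars follow the 0.10/0.05/0.01/0.001 scheme", {
  expect_equal(significance_stars(c(0.04, 0.0005, 0.5, 0.10, 0.01, 0.001)),
               c("**", "****", "", "*", "***", "****"))
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("response profile converts LS-means to percent of the species average", {
  fake <- structure(list(lsmeans = data.frame(
    cultivar = rep(c("A", "B"), each = 3),
    category = rep(c("low", "moderate", "high"), 2),
    lsmean = c(7000, 7000, 7000, 7350, 7000, 6650),
    se = 100)), class = "gxe_fit")
  prof <- response_profile(fake, c("A", "B"), species_mean = 7000)
  expect_equal(prof$percent_of_average[prof$cultivar == "A"], rep(100, 3))
  expect_equal(prof$percent_of_average[prof$cultivar == "B" &
                                         prof$category == "low"], 105)
  expect_error(response_profile(fake, "A", species_mean = 0), "positive")
})

test_that("max diff is the response spread signed by the species contrast", {
  fake <- structure(list(lsmeans = data.frame(
    cultivar = rep(c("A", "B"), each = 3),
    category = rep(c("low", "moderate", "high"), 2),
    lsmean = c(7000, 7000, 7300,    # A: high - low = +300
               7300, 7000, 7100),   # B: high - low = -200
    se = 100)), class = "gxe_fit")
  md <- max_diff(fake)
  expect_equal(md$magnitude, 500)
  ## species contrast: mean(high) - mean(low) = 7200 - 7150 = +50
  expect_equal(md$value, 500)
  ## raising B's low cell flips the species contrast and widens the spread
  fake$lsmeans$lsmean[4] <- 7800   # B: high - low = -700
  md2 <- max_diff(fake)
  expect_equal(md2$value, -1000)   # spread 300 - (-700), contrast negative
  ## identical cultivars give zero spread
  fake$lsmeans$lsmean <- rep(c(7000, 7000, 7200), 2)
  expect_equal(max_diff(fake)$magnitude, 0)
  ## single cultivar is undefined
  one <- structure(list(lsmeans = fake$lsmeans[1:3, ]), class = "gxe_fit")
  expect_true(is.na(max_diff(one)$value))
})

test_that("the gap rule requires significant E and non-significant GxE", {
  expect_true(classify_gap(p_e = 1e-4, p_gxe = 0.95)$gap)
  expect_false(classify_gap(p_e = 0.5, p_gxe = 0.5)$gap)
  expect_false(classify_gap(p_e = 1e-4, p_gxe = 0.01)$gap)
  expect_true(is.na(classify_gap(NA, 0.5)$gap))
  ## monotone in alpha_GxE: lowering it never turns a gap into a non-gap,
  ## so over decreasing alphas the gap indicator is non-decreasing
  for (p_gxe in c(0.02, 0.06, 0.5)) {
    gaps <- vapply(c(0.10, 0.05, 0.01),
                   function(a) classify_gap(1e-4, p_gxe, alpha_gxe = a)$gap,
                   logical(1))
    expect_true(all(diff(gaps) >= 0))
  }
})

test_that("species summaries count significant response diversity correctly", {
  mk <- function(p_e, p_gxe) {
    structure(list(p_E = p_e, p_GxE = p_gxe, F_G = 1, p_G = 0.5, F_E = 1,
                   F_GxE = 1, sigma2_unit = 1, sigma2_resid = 1,
                   lsmeans = NULL, n_obs = 10, n_cultivars = 2),
              class = "gxe_fit")
  }
  fits <- list(V1 = mk(0.01, 1), V2 = mk(0.5, 1), V3 = mk(0.01, 0.04),
               V4 = NULL)
  s <- summarize_species(fits, "timothy")
  expect_equal(s$n_sig_gxe, 1)
  expect_equal(s$failed, "V4")
  expect_equal(nrow(s$table), 3)
  expect_true(s$table$gap[s$table$variable_id == "V1"])
  expect_false(s$table$gap[s$table$variable_id == "V3"])
  ## every p_GxE = 1 means zero diversity count
  fits0 <- list(V1 = mk(0.01, 1), V2 = mk(0.01, 1))
  expect_equal(summarize_species(fits0, "x")$n_sig_gxe, 0)
})

test_that("printed significance resolves star codes and numeric p-values", {
  expect_true(printed_significant(0.04, NA, 0.05))
  expect_false(printed_significant(0.06, NA, 0.05))
  expect_true(printed_significant(NA, "**", 0.05))
  expect_false(printed_significant(NA, "*", 0.05))   # 0.10 tendency only
  expect_true(printed_significant(NA, "*", 0.10))
  expect_true(printed_significant(NA, "****", 0.05))
  expect_false(printed_significant(NA, NA, 0.05))
})
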