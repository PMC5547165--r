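test_that("subgroup slope matches hand-computed OLS on a fixed toy set", {
  d <- tibble::tibble(age_months = c(150, 170, 190, 210),
                      mean_thickness = c(3.1, 3.0, 2.9, 2.8))
  fit <- suppressWarnings(subgroup_slope(d))
  expect_equal(fit$slope, -0.005, tolerance = 1e-12)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(fit$r, -1, tolerance = 1e-12)
})

test_that("R-squared equals the squared Pearson correlation exactly", {
  withr::with_seed(12, {
    d <- tibble::tibble(age_months = runif(50, 144, 216))
    d$mean_thickness <- 3.1 - 0.002 * d$age_months + rnorm(50, 0, 0.1)
    fit <- subgroup_slope(d)
    expect_equal(fit$R2, cor(d$mean_thickness, d$age_months)^2,
                 tolerance = 1e-12)
  })
})

test_that("degenerate slope inputs raise errors", {
  expect_error(subgroup_slope(tibble::tibble(age_months = c(1, 2),
                                             mean_thickness = c(1, 2))),
               "at least 3")
  expect_error(subgroup_slope(tibble::tibble(age_months = rep(180, 5),
                                             mean_thickness = rnorm(5))),
               "zero variance")
})

test_that("three-way interaction F is invariant to shifting the age origin", {
  d <- toy_cohort(n_per_cell = 25, seed = 13)
  f1 <- fit_three_way(d, "F")
  d2 <- dplyr::mutate(d, age_months = age_months - 180)
  f2 <- fit_three_way(d2, "F")
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
  expect_equal(f1$p_raw, f2$p_raw, tolerance = 1e-8)
})

test_that("duplicating every family as identical siblings is absorbed", {
  d <- toy_cohort(n_per_cell = 20, seed = 14)
  f0 <- fit_three_way(d, "F") # singleton families: plain OLS
  dup <- dplyr::bind_rows(d, dplyr::mutate(d, participant_id = paste0(participant_id, "b")))
  # pooled OLS fixed effects are exactly unchanged by the duplication
  ols0 <- f0$fit
  prep <- function(x) dplyr::mutate(
    x, age_c = age_months - mean(age_months),
    income_group = factor(income_group, c("low", "high")),
    inequality_group = factor(inequality_group, c("low", "high")))
  ols1 <- lm(formula(ols0), data = prep(dup))
  expect_equal(unname(coef(ols1)), unname(coef(ols0)), tolerance = 1e-10)
  # cluster-robust slope contrasts are exactly unchanged
  c0 <- compare_slopes(d, "low_income.high_ineq", "high_income.low_ineq")
  c1 <- compare_slopes(dup, "low_income.high_ineq", "high_income.low_ineq")
  expect_equal(c1$slope_diff, c0$slope_diff, tolerance = 1e-10)
  # the mixed model pushes the duplication into the family intercept:
  # residual variance collapses, family variance carries the spread
  f1 <- fit_three_way(dup, "F")
  expect_s4_class(f1$fit, "merMod")
  vc <- as.data.frame(lme4::VarCorr(f1$fit))
  expect_lt(vc$sdcor[vc$grp == "Residual"], 1e-4)
  expect_gt(vc$sdcor[vc$grp == "family_id"], 0.01)
})

test_that("with no family variance the mixed fit agrees with OLS", {
  cfg <- small_config(seed = 15, family_sd = 0)
  gen <- generate_cohort(cfg, generate_tracts(cfg))
  co <- dplyr::inner_join(gen$cohort,
                          gen$truth$participant_truth[, c("participant_id",
                                                          "income_group",
                                                          "inequality_group",
                                                          "subgroup")],
                          by = "participant_id")
  f <- fit_three_way(co, "F")
  d <- co[co$sex == "F", ]
  d$income_group <- factor(d$income_group, levels = c("low", "high"))
  d$inequality_group <- factor(d$inequality_group, levels = c("low", "high"))
  d$age_c <- d$age_months - mean(d$age_months)
  ols <- lm(mean_thickness ~ age_c * income_group * inequality_group, data = d)
  expect_equal(unname(lme4::fixef(f$fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("empty design cells and degenerate factors are informative errors", {
  d <- toy_cohort(n_per_cell = 10, seed = 16)
  d1 <- d[!(d$income_group == "low" & d$inequality_group == "high"), ]
  expect_error(fit_three_way(d1, "F"), "income_group=low")
  d2 <- d[d$inequality_group == "low", ]
  expect_error(fit_age_by_inequality(dplyr::mutate(d2, income_group = "low"),
                                     "F", "low"),
               "one inequality group")
})

test_that("pairwise slope contrasts reject identical labels and detect differences", {
  d <- toy_cohort(n_per_cell = 40, seed = 17)
  expect_error(compare_slopes(d, "low_income.high_ineq", "low_income.high_ineq"),
               "Degenerate")
  # inject a steep slope into one subgroup
  steep <- d$subgroup == "low_income.high_ineq"
  d$mean_thickness[steep] <- d$mean_thickness[steep] -
    0.006 * (d$age_months[steep] - 180)
  out <- compare_all_slopes(d, sex = "F")
  expect_identical(nrow(out), 6L)
  lihi_rows <- out$subgroup_a == "low_income.high_ineq" |
    out$subgroup_b == "low_income.high_ineq"
  expect_true(all(out$p[lihi_rows] < 0.01))
  expect_true(all(out$p_fdr >= out$p - 1e-15))
})

test_that("adjustment replaces thickness by covariate residuals plus grand mean", {
  withr::with_seed(18, {
    n <- 400
    d <- tibble::tibble(
      parental_education = sample(1:9, n, TRUE),
      maternal_smoking = rbinom(n, 1, 0.25) == 1,
      mean_thickness = 3.1 + rnorm(n, 0, 0.1))
    # covariates independent of thickness: adjustment is near-identity
    adj <- adjust_thickness(d, thickness_cols = "mean_thickness")
    expect_gt(cor(adj$mean_thickness, d$mean_thickness), 0.99)
    # thickness an exact function of education: adjusted is constant
    d2 <- dplyr::mutate(d, mean_thickness = 0.05 * parental_education)
    adj2 <- adjust_thickness(d2, covariates = "parental_education",
                             thickness_cols = "mean_thickness")
    expect_lt(sd(adj2$mean_thickness), 1e-12)
    # constant covariate is skipped with a warning
    d3 <- dplyr::mutate(d, maternal_smoking = FALSE)
    expect_warning(adjust_thickness(d3, thickness_cols = "mean_thickness"),
                   "constant")
  })
})

test_that("age-squared sensitivity terms leave the model estimable", {
  d <- toy_cohort(n_per_cell = 30, seed = 19)
  f <- fit_three_way(d, "F", include_age2 = TRUE)
  expect_true(is.finite(f$F))
  expect_gt(f$df_den, 0)
})

test_that("FDR adjustment never lowers a p-value and respects BH", {
  d <- toy_cohort(n_per_cell = 30, seed = 20)
  res <- list(fit_three_way(d, "F"),
              fit_age_by_inequality(d, "F", "low"),
              fit_age_by_inequality(d, "F", "high"))
  out <- fdr_adjust(res)
  expect_equal(out$p_fdr, p.adjust(out$p_raw, "BH"))
  expect_true(all(out$p_fdr >= out$p_raw - 1e-15))
})
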