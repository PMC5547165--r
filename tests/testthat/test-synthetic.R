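test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 99)
  expect_identical(generate_tracts(cfg), generate_tracts(cfg))
  expect_identical(generate_expression(cfg), generate_expression(cfg))
  tr <- generate_tracts(cfg)
  expect_identical(generate_cohort(cfg, tr), generate_cohort(cfg, tr))
})

test_that("tract microdata Gini matches the lognormal closed form", {
  # all tracts share one sigma via a degenerate Gini range
  cfg <- small_config(seed = 31, gini_range = c(0.45, 0.45))
  tr <- generate_tracts(cfg)
  sigma <- sqrt(2) * qnorm((0.45 + 1) / 2)
  closed <- 2 * pnorm(sigma / sqrt(2)) - 1
  expect_true(all(tr$n_households >= 500))
  expect_true(all(abs(tr$gini_true - closed) < 0.02))
  # and across a spread of targets under the default range
  cfg2 <- small_config(seed = 32)
  tr2 <- generate_tracts(cfg2)
  targets <- seq(cfg2$gini_range[1], cfg2$gini_range[2],
                 length.out = cfg2$n_tracts)
  expect_true(all(abs(tr2$gini_true - targets) < 0.02))
})

test_that("zero lognormal scale gives perfectly equal incomes", {
  cfg <- small_config(seed = 33, gini_range = c(0, 0))
  tr <- generate_tracts(cfg)
  expect_true(all(abs(tr$gini_true) < 1e-12))
})

test_that("sibling rate zero yields unique family ids", {
  cfg <- small_config(seed = 34, sibling_rate = 0)
  gen <- generate_cohort(cfg, generate_tracts(cfg))
  expect_false(any(duplicated(gen$cohort$family_id)))
  # and a positive rate yields some two-child families
  cfg2 <- small_config(seed = 34, sibling_rate = 0.5)
  gen2 <- generate_cohort(cfg2, generate_tracts(cfg2))
  expect_true(any(duplicated(gen2$cohort$family_id)))
})

test_that("expression generator hits the target correlation", {
  cfg <- small_config(seed = 35)
  e <- generate_expression(cfg)
  expect_equal(cor(e$expr_NR3C1, e$expr_AR), 0.75, tolerance = 1e-10)
  expect_identical(e$region, dk_regions())

  e0 <- generate_expression(small_config(seed = 35, expression_correlation = 0))
  expect_lt(abs(cor(e0$expr_NR3C1, e0$expr_AR)), 0.08)

  e99 <- generate_expression(small_config(seed = 35,
                                          expression_correlation = 0.99))
  expect_gt(cor(e99$expr_NR3C1, e99$expr_AR), 0.95)

  es <- generate_expression(cfg, method = "sample")
  expect_lt(abs(cor(es$expr_NR3C1, es$expr_AR) - 0.75), 0.08)

  expect_error(sim_config(expression_correlation = 1), "< 1")
})

test_that("ages, families and incomes respect the configured design", {
  cfg <- small_config(seed = 36)
  gen <- generate_cohort(cfg, generate_tracts(cfg))
  co <- gen$cohort
  expect_true(all(co$age_months >= 144 & co$age_months <= 216))
  expect_setequal(unique(co$sex), c("F", "M"))
  # siblings share family-level variables
  fam <- dplyr::add_count(co, family_id)
  sib <- fam[fam$n == 2, ]
  agree <- tapply(sib$household_income, sib$family_id,
                  function(v) diff(range(v)) == 0)
  expect_true(all(agree))
  # truth income split is ~50/50 by construction
  tt <- gen$truth$participant_truth
  expect_lt(abs(mean(tt$income_group == "low") - 0.5), 0.01)
})

test_that("true subgroup slopes are recovered within two standard errors", {
  # parameter recovery with the true grouping, across seeds
  hits <- 0; total <- 0
  for (seed in 1:25) {
    cfg <- small_config(seed = seed, n_families = 80L)
    gen <- generate_cohort(cfg, generate_tracts(cfg))
    co <- dplyr::inner_join(
      gen$cohort,
      gen$truth$participant_truth[, c("participant_id", "subgroup")],
      by = "participant_id")
    for (sx in c("F", "M")) {
      est <- subgroup_slopes(co, sex = sx)
      truth <- gen$truth$subgroup_slopes[[sx]][est$subgroup]
      hits <- hits + sum(abs(est$slope - truth) <= 2 * est$se)
      total <- total + nrow(est)
    }
  }
  expect_gte(hits / total, 0.90)
})

test_that("a deliberately steeper subgroup is steepest downstream in most seeds", {
  sg <- subgroup_levels()
  steep <- stats::setNames(c(-0.004, -0.001, -0.001, -0.001), sg)
  wins <- 0
  for (seed in 1:15) {
    cfg <- small_config(seed = seed, n_families = 80L,
                        subgroup_slopes = list(F = steep, M = steep),
                        expr_association = list(F = steep * 0, M = steep * 0))
    tr <- generate_tracts(cfg)
    gen <- generate_cohort(cfg, tr)
    tr2 <- assign_inequality(tr, cfg$bin_edges)
    co <- assign_subgroups(gen$cohort, tr2, cfg$lico)
    est <- subgroup_slopes(co, sex = "F")
    if (est$subgroup[which.min(est$slope)] == "low_income.high_ineq") {
      wins <- wins + 1
    }
  }
  expect_gt(wins / 15, 0.5)
})

test_that("the written study round-trips through CSV and JSON", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 37)
  paths <- write_synthetic_study(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  co <- readr::read_csv(paths$cohort, show_col_types = FALSE)
  expect_identical(nrow(co), nrow(generate_cohort(cfg, generate_tracts(cfg))$cohort))
  truth <- jsonlite::read_json(paths$truth)
  expect_named(truth, c("subgroup_slopes", "expr_association", "tract_truth",
                        "participant_truth"), ignore.order = TRUE)
})
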