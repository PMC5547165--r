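make_profiles <- function(z_by_subgroup, expr = NULL, n_regions = 34,
                          sex = "F") {
  expr <- expr %||% seq_len(n_regions)
  purrr::imap_dfr(z_by_subgroup, function(z, sg) {
    parts <- strsplit(sg, "[._]")[[1]]
    tibble::tibble(sex = sex, subgroup = sg,
                   income_group = parts[1], inequality_group = parts[3],
                   region = paste0("r", seq_len(n_regions)),
                   n = 100, r = tanh(z), z = z,
                   expr_NR3C1 = expr, expr_AR = expr)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Fisher z matches its closed form, is odd, increasing, invertible", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(0.5), 0.5 * (log(1.5) - log(0.5)), tolerance = 1e-15)
  grid <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z_inv(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_equal(fisher_z(-grid), -fisher_z(grid), tolerance = 1e-15)
  expect_true(all(diff(fisher_z(grid)) > 0))
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("subgroup profile fit reproduces a hand OLS on a 5-region toy set", {
  profs <- make_profiles(list(low_income.high_ineq = -0.1 * (1:5)),
                         expr = 1:5, n_regions = 5)
  fit <- suppressWarnings(
    subgroup_profile_fit(profs, "NR3C1", "low_income.high_ineq"))
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
})

test_that("identical z profiles across subgroups give a null three-way term", {
  z <- sin(seq_len(34)) * 0.1 - 0.2
  profs <- make_profiles(stats::setNames(list(z, z, z, z), subgroup_levels()),
                         expr = rnorm(34))
  f <- fit_profile_three_way(profs, "NR3C1", "F")
  expect_lt(f$F, 1e-18)
  expect_identical(f$n, 136L)
  expect_identical(f$df_den, 128L)
  expect_identical(fit_profile_three_way(profs, "NR3C1", "F",
                                         df = "printed")$df_den, 134L)
})

test_that("profile statistics are invariant to region order and expression units", {
  withr::with_seed(23, {
    zs <- lapply(1:4, function(i) rnorm(34, -0.2, 0.1))
    names(zs) <- subgroup_levels()
    profs <- make_profiles(zs, expr = rnorm(34, 7, 0.5))
    f0 <- fit_profile_three_way(profs, "NR3C1", "F")
    shuffled <- profs[sample(nrow(profs)), ]
    f1 <- fit_profile_three_way(shuffled, "NR3C1", "F")
    expect_equal(f0$F, f1$F, tolerance = 1e-10)
    rescaled <- dplyr::mutate(profs, expr_NR3C1 = 3 + 40 * expr_NR3C1)
    f2 <- fit_profile_three_way(rescaled, "NR3C1", "F")
    expect_equal(f0$F, f2$F, tolerance = 1e-8)
    expect_equal(f0$R2, f2$R2, tolerance = 1e-10)
    w0 <- fit_profile_within_income(profs, "NR3C1", "F", "low")
    w1 <- fit_profile_within_income(rescaled, "NR3C1", "F", "low")
    expect_equal(w0$F, w1$F, tolerance = 1e-8)
  })
})

test_that("stacked factorial cell slopes reproduce the subgroup simple fits", {
  withr::with_seed(24, {
    zs <- lapply(1:4, function(i) rnorm(34, -0.2, 0.1))
    names(zs) <- subgroup_levels()
    profs <- make_profiles(zs, expr = rnorm(34, 7, 0.5))
    f <- fit_profile_three_way(profs, "NR3C1", "F")
    b <- coef(f$fit)
    cell_slope <- c(
      low_low = unname(b["expr"]),
      low_high = unname(b["expr"] + b["expr:inequality_grouphigh"]),
      high_low = unname(b["expr"] + b["expr:income_grouphigh"]),
      high_high = unname(b["expr"] + b["expr:income_grouphigh"] +
                           b["expr:inequality_grouphigh"] +
                           b["expr:income_grouphigh:inequality_grouphigh"]))
    fits <- subgroup_profile_fits(profs, "NR3C1")
    for (sg in fits$subgroup) {
      parts <- strsplit(sg, "[._]")[[1]]
      key <- paste(parts[1], parts[3], sep = "_")
      expect_equal(fits$slope[fits$subgroup == sg], cell_slope[[key]],
                   tolerance = 1e-10)
    }
  })
})

test_that("regional correlations equal the global one when regions copy it", {
  withr::with_seed(25, {
    n <- 60
    d <- tibble::tibble(
      participant_id = sprintf("P%02d", 1:n), sex = "F",
      subgroup = "low_income.high_ineq",
      age_months = runif(n, 144, 216))
    d$mean_thickness <- 3.1 - 0.003 * d$age_months + rnorm(n, 0, 0.1)
    for (reg in dk_regions()[1:5]) d[[paste0("thk_", reg)]] <- d$mean_thickness
    rc <- regional_age_correlations(d, "low_income.high_ineq")
    expect_equal(rc$r, rep(cor(d$mean_thickness, d$age_months), 5),
                 tolerance = 1e-12)
    d$thk_bankssts <- 2.5
    expect_error(regional_age_correlations(d, "low_income.high_ineq"),
                 "bankssts")
  })
})

test_that("gene-gene profile correlation behaves on exact cases", {
  e <- tibble::tibble(region = paste0("r", 1:34),
                      expr_NR3C1 = rnorm(34, 7, 0.5))
  e$expr_AR <- e$expr_NR3C1
  expect_equal(expression_gene_correlation(e)$r, 1, tolerance = 1e-12)
  e$expr_AR <- -e$expr_NR3C1
  expect_equal(expression_gene_correlation(e)$r, -1, tolerance = 1e-12)
  e$expr_AR <- 5
  expect_error(expression_gene_correlation(e), "constant")
})

test_that("profile fits validate their inputs", {
  zs <- lapply(1:3, function(i) rnorm(34))
  names(zs) <- subgroup_levels()[1:3]
  profs <- make_profiles(zs)
  expect_error(fit_profile_three_way(profs, "NR3C1", "F"), "four subgroups")
  expect_error(fit_profile_within_income(profs, "NR3C1", "F", "middle"),
               "low")
  expect_error(fit_profile_three_way(profs, "BDNF", "F"), "BDNF")
})
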