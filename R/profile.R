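#' Fisher z-transformation of a correlation coefficient
#'
#' \eqn{z = 0.5[\ln(1+r) - \ln(1-r)]}, the variance-stabilizing transform
#' that maps Pearson correlations to an approximately normal scale.
#' [fisher_z_inv()] is the inverse (`tanh`).
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @param z Fisher z value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("Fisher z is defined only for |r| < 1.", call. = FALSE)
  }
  0.5 * (log1p(r) - log1p(-r))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Regional thickness-age correlations within a subgroup
#'
#' Pearson correlation of each of the 34 regional thickness measures with
#' age, within one subgroup (optionally one sex), together with the Fisher
#' z-transform of each correlation.
#'
#' @param cohort Cohort tibble with `age_months` and `thk_<region>` columns.
#' @param subgroup Subgroup label to filter on, or `NULL` for all rows.
#' @param sex Optional sex filter.
#' @return Tibble with `region`, `n`, `r`, `z`, one row per region.
#' @export
regional_age_correlations <- function(cohort, subgroup = NULL, sex = NULL) {
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (!is.null(subgroup)) d <- d[d$subgroup == subgroup, ]
  if (nrow(d) < 3) stop("Need at least 3 participants per subgroup.", call. = FALSE)
  cols <- grep("^thk_", names(d), value = TRUE)
  if (length(cols) == 0) stop("No regional thickness (`thk_*`) columns found.",
                              call. = FALSE)
  constant <- cols[vapply(cols, function(cl) stats::sd(d[[cl]]) == 0, logical(1))]
  if (length(constant) > 0) {
    stop("Regional thickness constant within subgroup: ",
         paste(sub("^thk_", "", constant), collapse = ", "), call. = FALSE)
  }
  r <- vapply(cols, function(cl) stats::cor(d[[cl]], d$age_months), numeric(1))
  tibble::tibble(region = sub("^thk_", "", cols), n = nrow(d),
                 r = unname(r), z = fisher_z(unname(r)))
}

#' Build per-region correlation profiles for every sex-by-subgroup cell
#'
#' Computes [regional_age_correlations()] for each subgroup within each sex
#' and joins the region-expression table, yielding the stacked long table
#' used by the profile regressions.
#'
#' @param cohort Cohort tibble with `sex` and `subgroup` columns.
#' @param expression Region-expression tibble with columns `region`,
#'   `expr_NR3C1`, `expr_AR`.
#' @return Tibble with `sex`, `subgroup`, `income_group`,
#'   `inequality_group`, `region`, `n`, `r`, `z`, `expr_NR3C1`, `expr_AR`.
#' @export
build_region_profiles <- function(cohort, expression) {
  stopifnot(all(c("region", "expr_NR3C1", "expr_AR") %in% names(expression)))
  d <- tibble::as_tibble(cohort)
  cells <- dplyr::distinct(d, .data$sex, .data$subgroup,
                           .data$income_group, .data$inequality_group)
  out <- purrr::pmap_dfr(cells, function(sex, subgroup, income_group,
                                         inequality_group) {
    prof <- regional_age_correlations(d, subgroup = subgroup, sex = sex)
    prof$sex <- sex
    prof$subgroup <- subgroup
    prof$income_group <- income_group
    prof$inequality_group <- inequality_group
    prof
  })
  missing <- setdiff(out$region, expression$region)
  if (length(missing) > 0) {
    stop("Regions missing from expression table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(out, expression, by = "region")
}

prep_profile_data <- function(profiles, gene, sex = NULL, income_group = NULL) {
  d <- tibble::as_tibble(profiles)
  gcol <- paste0("expr_", gene)
  if (!gcol %in% names(d)) {
    stop("Gene `", gene, "` not found (expected column `", gcol, "`).",
         call. = FALSE)
  }
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (!is.null(income_group)) d <- d[d$income_group == income_group, ]
  d$expr <- d[[gcol]]
  for (f in intersect(c("income_group", "inequality_group"), names(d))) {
    d[[f]] <- factor(d[[f]], levels = c("low", "high"))
  }
  d
}

new_profile_result <- function(gene, scope, term, F, df_num, df_den, p_raw,
                               R2, n, slope = NA_real_, fit = NULL) {
  structure(
    list(gene = gene, scope = scope, term = term, F = F, df_num = df_num,
         df_den = df_den, p_raw = p_raw, p_fdr = NA_real_, R2 = R2,
         slope = slope, n = n, fit = fit),
    class = c("ng_profile", "ng_interaction")
  )
}

#' @method tidy ng_profile
#' @export
tidy.ng_profile <- function(x, ...) {
  tibble::tibble(gene = x$gene, scope = x$scope, term = x$term, F = x$F,
                 df_num = x$df_num, df_den = x$df_den, p_raw = x$p_raw,
                 p_fdr = x$p_fdr, R2 = x$R2, slope = x$slope, n = x$n)
}

#' Expression-by-income-by-inequality interaction on z profiles
#'
#' Stacks the four subgroup profiles of one sex (4 subgroups x 34 regions =
#' 136 observations) and regresses the Fisher z values on the full
#' factorial of gene expression, income group and inequality group by OLS,
#' returning the Wald F for the three-way term. Regions are treated as
#' independent observations.
#'
#' @param profiles Output of [build_region_profiles()].
#' @param gene `"NR3C1"` or `"AR"`.
#' @param sex `"F"` or `"M"`.
#' @param df Denominator df convention: `"residual"` (n minus number of
#'   coefficients, default) or `"printed"` (n - 2).
#' @return An `ng_profile` result (tidies to one row).
#' @export
fit_profile_three_way <- function(profiles, gene, sex,
                                  df = c("residual", "printed")) {
  df <- match.arg(df)
  d <- prep_profile_data(profiles, gene, sex = sex)
  if (length(unique(d$subgroup)) != 4) {
    stop("All four subgroups are required; found: ",
         paste(unique(d$subgroup), collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(z ~ expr * income_group * inequality_group, data = d)
  w <- wald_f_term(fit, "expr:income_grouphigh:inequality_grouphigh",
                   n = nrow(d), df = df)
  new_profile_result(gene = gene, scope = "three_way",
                     term = "expression:income:inequality",
                     F = w$F, df_num = w$df_num, df_den = w$df_den,
                     p_raw = w$p, R2 = summary(fit)$r.squared, n = nrow(d),
                     fit = fit)
}

#' Expression-by-inequality interaction within one income group
#'
#' As [fit_profile_three_way()] restricted to one income group (2 subgroups
#' x 34 regions = 68 observations), testing the expression-by-inequality
#' term.
#'
#' @inheritParams fit_profile_three_way
#' @param income_group `"low"` or `"high"`.
#' @return An `ng_profile` result.
#' @export
fit_profile_within_income <- function(profiles, gene, sex, income_group,
                                      df = c("residual", "printed")) {
  df <- match.arg(df)
  if (!income_group %in% c("low", "high")) {
    stop("`income_group` must be \"low\" or \"high\".", call. = FALSE)
  }
  d <- prep_profile_data(profiles, gene, sex = sex, income_group = income_group)
  if (length(unique(as.character(d$inequality_group))) != 2) {
    stop("Both inequality groups are required within the income group.",
         call. = FALSE)
  }
  fit <- stats::lm(z ~ expr * inequality_group, data = d)
  w <- wald_f_term(fit, "expr:inequality_grouphigh", n = nrow(d), df = df)
  new_profile_result(gene = gene, scope = paste0("within_", income_group, "_income"),
                     term = "expression:inequality",
                     F = w$F, df_num = w$df_num, df_den = w$df_den,
                     p_raw = w$p, R2 = summary(fit)$r.squared, n = nrow(d),
                     fit = fit)
}

#' Simple expression-profile fit within one subgroup
#'
#' OLS of the 34 Fisher z values of one subgroup on one gene's expression
#' profile: slope, R-squared and the two-sided p-value.
#'
#' @inheritParams fit_profile_three_way
#' @param subgroup Subgroup label.
#' @return An `ng_profile` result carrying `slope` and `R2`.
#' @export
subgroup_profile_fit <- function(profiles, gene, subgroup, sex = NULL) {
  d <- prep_profile_data(profiles, gene, sex = sex)
  d <- d[d$subgroup == subgroup, ]
  if (nrow(d) < 3) stop("Need at least 3 regions.", call. = FALSE)
  if (stats::sd(d$expr) == 0) {
    stop("Expression is constant across regions.", call. = FALSE)
  }
  fit <- stats::lm(z ~ expr, data = d)
  s <- summary(fit)
  co <- s$coefficients["expr", ]
  res <- new_profile_result(
    gene = gene, scope = "subgroup_simple", term = "expression",
    F = unname(co["t value"])^2, df_num = 1L,
    df_den = as.integer(fit$df.residual), p_raw = unname(co["Pr(>|t|)"]),
    R2 = s$r.squared, n = nrow(d), slope = unname(co["Estimate"]), fit = fit)
  res$subgroup <- subgroup
  res
}

#' R-squared of the expression-profile fit for every subgroup
#'
#' @inheritParams fit_profile_three_way
#' @return Tibble with `subgroup`, `slope`, `R2`, `p`, `n` rows per subgroup.
#' @export
subgroup_profile_fits <- function(profiles, gene, sex = NULL) {
  d <- tibble::as_tibble(profiles)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  purrr::map_dfr(intersect(subgroup_levels(), unique(d$subgroup)), function(g) {
    f <- subgroup_profile_fit(d, gene, g)
    tibble::tibble(subgroup = g, slope = f$slope, R2 = f$R2, p = f$p_raw, n = f$n)
  })
}

#' Correlation between the two receptor expression profiles
#'
#' Pearson correlation (with two-sided p) between NR3C1 and AR expression
#' across the cortical regions.
#'
#' @param expr_table Tibble with `region`, `expr_NR3C1`, `expr_AR`.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
expression_gene_correlation <- function(expr_table) {
  stopifnot(all(c("expr_NR3C1", "expr_AR") %in% names(expr_table)))
  x <- expr_table$expr_NR3C1
  y <- expr_table$expr_AR
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Expression column is constant across regions.", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
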