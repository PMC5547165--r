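#' @importFrom generics tidy glance
NULL

new_interaction_result <- function(term, F, df_num, df_den, p_raw, n,
                                   descriptor, fit) {
  structure(
    list(term = term, F = F, df_num = df_num, df_den = df_den,
         p_raw = p_raw, p_fdr = NA_real_, n = n,
         model_descriptor = descriptor, fit = fit),
    class = "ng_interaction"
  )
}

#' @export
print.ng_interaction <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$term, x$df_num, x$df_den, x$F, x$p_raw, x$n))
  invisible(x)
}

#' Tidy an interaction test result
#'
#' @param x An `ng_interaction` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `F`, `df_num`, `df_den`, `p_raw`,
#'   `p_fdr`, `n`, `model_descriptor`.
#' @method tidy ng_interaction
#' @export
tidy.ng_interaction <- function(x, ...) {
  tibble::tibble(term = x$term, F = x$F, df_num = x$df_num, df_den = x$df_den,
                 p_raw = x$p_raw, p_fdr = x$p_fdr, n = x$n,
                 model_descriptor = x$model_descriptor)
}

#' @method glance ng_interaction
#' @export
glance.ng_interaction <- function(x, ...) {
  tibble::tibble(n = x$n, df_den = x$df_den, model_descriptor = x$model_descriptor)
}

# Wald F (t^2) for a single fixed-effect coefficient of a merMod or lm fit.
wald_f_term <- function(fit, coef_name, n, df = c("residual", "printed")) {
  df <- match.arg(df)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  if (!coef_name %in% names(b)) {
    stop("Coefficient `", coef_name, "` not found in model; available: ",
         paste(names(b), collapse = ", "), call. = FALSE)
  }
  Fstat <- unname(b[coef_name]^2 / V[coef_name, coef_name])
  df_den <- if (df == "residual") n - length(b) else n - 2L
  list(F = Fstat, df_num = 1L, df_den = as.integer(df_den),
       p = stats::pf(Fstat, 1, df_den, lower.tail = FALSE))
}

check_cells <- function(data, factors, min_n = 2L) {
  tab <- table(data[factors])
  if (any(tab < min_n)) {
    bad <- which(tab < min_n, arr.ind = TRUE)
    lab <- apply(bad, 1, function(i) {
      paste(mapply(function(f, j) paste0(f, "=", dimnames(tab)[[f]][j]),
                   factors, i), collapse = ", ")
    })
    stop("Design cell(s) with fewer than ", min_n, " participants: ",
         paste(lab, collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

prep_model_data <- function(cohort, sex = NULL, income_group = NULL) {
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (!is.null(income_group)) d <- d[d$income_group == income_group, ]
  for (f in intersect(c("income_group", "inequality_group"), names(d))) {
    d[[f]] <- factor(d[[f]], levels = c("low", "high"))
  }
  d$age_c <- d$age_months - mean(d$age_months)
  d
}

fit_nested <- function(formula, data) {
  if (length(unique(data$family_id)) < nrow(data)) {
    f <- stats::update(formula, . ~ . + (1 | family_id))
    suppressMessages(lme4::lmer(f, data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
  } else {
    # no nesting present: a random intercept is unidentified, fall back to OLS
    stats::lm(formula, data = data)
  }
}

#' Age-by-income-by-inequality interaction on mean cortical thickness
#'
#' Fits, within one sex, a linear model of mean cortical thickness with the
#' full factorial of age (months, centered internally), income group and
#' inequality group as fixed effects and a family-level random intercept
#' (adolescents nested in families), then returns the Wald F test of the
#' three-way interaction.
#'
#' @param cohort Cohort tibble with `mean_thickness`, `age_months`, `sex`,
#'   `income_group`, `inequality_group`, `family_id`.
#' @param sex `"F"` or `"M"`; the model is fitted within this stratum.
#' @param include_age2 Also include an age-squared term and its interactions
#'   with income and income-by-inequality (sensitivity analysis).
#' @param df Denominator degrees of freedom convention: `"residual"`
#'   (n minus the number of fixed coefficients, default) or `"printed"`
#'   (n - 2).
#' @return An `ng_interaction` object (see [tidy.ng_interaction()]).
#' @export
fit_three_way <- function(cohort, sex, include_age2 = FALSE,
                          df = c("residual", "printed")) {
  df <- match.arg(df)
  d <- prep_model_data(cohort, sex = sex)
  check_cells(d, c("income_group", "inequality_group"))
  rhs <- "age_c * income_group * inequality_group"
  if (include_age2) {
    rhs <- paste(rhs, "+ I(age_c^2) + I(age_c^2):income_group",
                 "+ I(age_c^2):income_group:inequality_group")
  }
  fml <- stats::as.formula(paste("mean_thickness ~", rhs))
  check_fixed_rank(fml, d)
  fit <- fit_nested(fml, d)
  w <- wald_f_term(fit, "age_c:income_grouphigh:inequality_grouphigh",
                   n = nrow(d), df = df)
  new_interaction_result(
    term = "age:income:inequality", F = w$F, df_num = w$df_num,
    df_den = w$df_den, p_raw = w$p, n = nrow(d),
    descriptor = paste0("mean_thickness ~ ", rhs,
                        " + (1|family_id); sex=", sex),
    fit = fit)
}

check_fixed_rank <- function(formula, data) {
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(deparse(formula[[3]]), collapse = " "))),
    data = data)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    stop("Fixed-effect design is rank deficient (rank ", q$rank, " < ",
         ncol(X), " columns); condition number ", format(kappa(X), digits = 3),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Age-by-inequality interaction within one income group
#'
#' Follow-up to [fit_three_way()]: within one sex and one income group,
#' tests the age-by-inequality interaction on mean cortical thickness with
#' the same family-nested model structure.
#'
#' @inheritParams fit_three_way
#' @param income_group `"low"` or `"high"`.
#' @return An `ng_interaction` object.
#' @export
fit_age_by_inequality <- function(cohort, sex, income_group,
                                  df = c("residual", "printed")) {
  df <- match.arg(df)
  d <- prep_model_data(cohort, sex = sex, income_group = income_group)
  if (length(unique(as.character(d$inequality_group))) < 2) {
    stop("Only one inequality group present; the interaction is degenerate.",
         call. = FALSE)
  }
  check_cells(d, "inequality_group")
  fml <- mean_thickness ~ age_c * inequality_group
  fit <- fit_nested(fml, d)
  w <- wald_f_term(fit, "age_c:inequality_grouphigh", n = nrow(d), df = df)
  new_interaction_result(
    term = "age:inequality", F = w$F, df_num = w$df_num, df_den = w$df_den,
    p_raw = w$p, n = nrow(d),
    descriptor = paste0("mean_thickness ~ age_c * inequality_group + ",
                        "(1|family_id); sex=", sex, "; income=", income_group),
    fit = fit)
}

#' Preliminary age-by-sex interaction on the pooled sample
#'
#' Gatekeeper test motivating sex-stratified analyses: age-by-sex
#' interaction on mean cortical thickness over the pooled cohort, with a
#' family random intercept.
#'
#' @inheritParams fit_three_way
#' @return An `ng_interaction` object.
#' @export
fit_age_by_sex <- function(cohort, df = c("residual", "printed")) {
  df <- match.arg(df)
  d <- prep_model_data(cohort)
  d$sex <- factor(d$sex, levels = c("F", "M"))
  fit <- fit_nested(mean_thickness ~ age_c * sex, d)
  w <- wald_f_term(fit, "age_c:sexM", n = nrow(d), df = df)
  new_interaction_result(
    term = "age:sex", F = w$F, df_num = w$df_num, df_den = w$df_den,
    p_raw = w$p, n = nrow(d),
    descriptor = "mean_thickness ~ age_c * sex + (1|family_id); pooled",
    fit = fit)
}

#' Thickness-age slope within one subgroup
#'
#' Ordinary least-squares fit of mean cortical thickness on age (months)
#' within a subgroup, reported with the Pearson correlation, its square,
#' and the two-sided p-value.
#'
#' @param cohort Cohort tibble (see [fit_three_way()]).
#' @param subgroup A subgroup label (see [subgroup_levels()]), or `NULL` to
#'   use all rows of `cohort` as one group.
#' @param sex Optional sex filter applied before the subgroup filter.
#' @return One-row tibble: `subgroup`, `n`, `slope` (mm/month), `se`, `r`,
#'   `R2`, `p`.
#' @export
subgroup_slope <- function(cohort, subgroup = NULL, sex = NULL) {
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (!is.null(subgroup)) d <- d[d$subgroup == subgroup, ]
  if (nrow(d) < 3) stop("Need at least 3 participants to fit a slope.", call. = FALSE)
  if (stats::sd(d$age_months) == 0) {
    stop("Age has zero variance in this subgroup.", call. = FALSE)
  }
  fit <- stats::lm(mean_thickness ~ age_months, data = d)
  s <- summary(fit)$coefficients["age_months", ]
  r <- stats::cor(d$mean_thickness, d$age_months)
  tibble::tibble(subgroup = subgroup %||% "all", n = nrow(d),
                 slope = unname(s["Estimate"]), se = unname(s["Std. Error"]),
                 r = r, R2 = r^2, p = unname(s["Pr(>|t|)"]))
}

#' Thickness-age slopes for every subgroup
#'
#' @inheritParams subgroup_slope
#' @return Tibble with one row per subgroup present, columns as in
#'   [subgroup_slope()].
#' @export
subgroup_slopes <- function(cohort, sex = NULL) {
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  purrr::map_dfr(intersect(subgroup_levels(), unique(d$subgroup)),
                 function(g) subgroup_slope(d, g))
}

#' Pairwise comparison of thickness-age slopes between subgroups
#'
#' Pools two subgroups and fits `mean_thickness ~ age * subgroup` by OLS
#' with family-clustered (CR0) robust standard errors; the two-sided Wald
#' p-value of the age-by-subgroup coefficient tests equality of slopes.
#'
#' @inheritParams subgroup_slope
#' @param subgroup_a,subgroup_b Distinct subgroup labels.
#' @return One-row tibble: `subgroup_a`, `subgroup_b`, `slope_diff`, `se`,
#'   `statistic`, `p`, `n`.
#' @export
compare_slopes <- function(cohort, subgroup_a, subgroup_b, sex = NULL) {
  if (identical(subgroup_a, subgroup_b)) {
    stop("Degenerate contrast: the two subgroups are identical.", call. = FALSE)
  }
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  d <- d[d$subgroup %in% c(subgroup_a, subgroup_b), ]
  if (!all(c(subgroup_a, subgroup_b) %in% d$subgroup)) {
    stop("Both subgroups must be populated.", call. = FALSE)
  }
  d$subgroup <- factor(d$subgroup, levels = c(subgroup_a, subgroup_b))
  d$age_c <- d$age_months - mean(d$age_months)
  fit <- stats::lm(mean_thickness ~ age_c * subgroup, data = d)
  V <- sandwich::vcovCL(fit, cluster = d$family_id)
  ct <- lmtest::coeftest(fit, vcov. = V)
  cn <- paste0("age_c:subgroup", subgroup_b)
  tibble::tibble(subgroup_a = subgroup_a, subgroup_b = subgroup_b,
                 slope_diff = unname(ct[cn, "Estimate"]),
                 se = unname(ct[cn, "Std. Error"]),
                 statistic = unname(ct[cn, "t value"]),
                 p = unname(ct[cn, "Pr(>|t|)"]), n = nrow(d))
}

#' All six pairwise slope contrasts within one sex, FDR-adjusted
#'
#' Runs [compare_slopes()] for every pair of populated subgroups and
#' adjusts the p-values with Benjamini-Hochberg as one test family.
#'
#' @inheritParams subgroup_slope
#' @return Tibble of contrasts with a `p_fdr` column.
#' @export
compare_all_slopes <- function(cohort, sex = NULL) {
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  groups <- intersect(subgroup_levels(), unique(d$subgroup))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) compare_slopes(d, p[1], p[2]))
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Adjust thickness measures for covariates
#'
#' Replaces each thickness column by the residuals of an OLS regression on
#' the covariates, plus the grand mean (so the scale is preserved).
#' Covariates constant in the data are skipped with a warning.
#'
#' @param cohort Cohort tibble.
#' @param covariates Covariate column names; default parental education and
#'   maternal smoking.
#' @param thickness_cols Columns to adjust; defaults to `mean_thickness`
#'   plus every `thk_*` regional column.
#' @return `cohort` with the thickness columns replaced by adjusted values.
#' @export
adjust_thickness <- function(cohort,
                             covariates = c("parental_education", "maternal_smoking"),
                             thickness_cols = NULL) {
  d <- tibble::as_tibble(cohort)
  stopifnot(all(covariates %in% names(d)))
  keep <- vapply(covariates, function(v) {
    ok <- length(unique(d[[v]])) > 1
    if (!ok) warning("Covariate `", v, "` is constant; skipped.", call. = FALSE)
    ok
  }, logical(1))
  covariates <- covariates[keep]
  if (length(covariates) == 0) return(d)
  if (is.null(thickness_cols)) {
    thickness_cols <- c("mean_thickness", grep("^thk_", names(d), value = TRUE))
    thickness_cols <- intersect(thickness_cols, names(d))
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))), data = d)
  for (col in thickness_cols) {
    fit <- stats::lm.fit(X, d[[col]])
    d[[col]] <- fit$residuals + mean(d[[col]])
  }
  d
}

#' Benjamini-Hochberg adjustment over a family of interaction results
#'
#' @param results A list of `ng_interaction` objects or a tidy tibble with a
#'   `p_raw` column.
#' @param alpha Significance level recorded alongside (informational).
#' @return Tidy tibble with `p_fdr` filled in.
#' @export
fdr_adjust <- function(results, alpha = 0.05) {
  tbl <- if (tibble::is_tibble(results) || is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    purrr::map_dfr(results, tidy)
  }
  tbl$p_fdr <- stats::p.adjust(tbl$p_raw, method = "BH")
  attr(tbl, "alpha") <- alpha
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
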