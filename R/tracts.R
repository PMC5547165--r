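#' Residualize tract Gini coefficients on neighborhood mean income
#'
#' Inequality and overall wealth are entangled at the neighborhood level; to
#' isolate inequality the tract Gini coefficient is adjusted for tract mean
#' household income before grouping. The default regresses Gini on mean
#' income by ordinary least squares (intercept included) and keeps the
#' residuals; `direction = "income_on_gini"` implements the reverse reading.
#'
#' @param tracts Tract tibble with `gini` and `mean_income` columns and at
#'   least 3 rows.
#' @param direction `"gini_on_income"` (default) or `"income_on_gini"`.
#' @return `tracts` with a `gini_residual` column. Residuals sum to ~0.
#' @export
residualize_gini <- function(tracts,
                             direction = c("gini_on_income", "income_on_gini")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gini", "mean_income") %in% names(tracts)))
  if (nrow(tracts) < 3) {
    stop("Need at least 3 tracts to residualize.", call. = FALSE)
  }
  tracts <- tibble::as_tibble(tracts)
  y <- if (direction == "gini_on_income") tracts$gini else tracts$mean_income
  x <- if (direction == "gini_on_income") tracts$mean_income else tracts$gini
  if (stats::sd(x) == 0) {
    warning("Predictor is constant across tracts; residuals are the centered response.",
            call. = FALSE)
    tracts$gini_residual <- y - mean(y)
  } else {
    tracts$gini_residual <- unname(stats::resid(stats::lm(y ~ x)))
  }
  tracts
}

#' Median split with ties going to the low group
#'
#' Splits values at their median: values strictly greater than the median are
#' labelled high, values less than or equal to the median low. With an odd
#' number of observations the median element itself therefore falls in the
#' low group (e.g. 37 tracts split 19 low / 18 high).
#'
#' @param values Numeric vector, length at least 2.
#' @param labels Two labels, `c(low, high)`.
#' @return Character vector of group labels, same length as `values`.
#' @export
median_split <- function(values, labels = c("low", "high")) {
  if (length(values) < 2) {
    stop("Need at least 2 values for a median split.", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA.", call. = FALSE)
  m <- stats::median(values)
  if (all(values == values[1])) {
    warning("All values identical; every observation assigned to the low group.",
            call. = FALSE)
    return(rep(labels[1], length(values)))
  }
  ifelse(values > m, labels[2], labels[1])
}

#' Assign tracts to high/low inequality groups
#'
#' Convenience wrapper running the inequality stage end-to-end on a tract
#' table: Gini estimation from bins, residualization on mean income, and the
#' ties-to-low median split into `inequality_group`.
#'
#' @inheritParams add_gini
#' @inheritParams residualize_gini
#' @return Tract tibble with `gini`, `gini_residual` and `inequality_group`
#'   columns.
#' @export
assign_inequality <- function(tracts, bin_edges,
                              method = c("lognormal_mle", "midpoint"),
                              direction = c("gini_on_income", "income_on_gini")) {
  tracts <- add_gini(tracts, bin_edges, method = match.arg(method))
  tracts <- residualize_gini(tracts, direction = match.arg(direction))
  tracts$inequality_group <- median_split(tracts$gini_residual)
  tracts
}

#' Compare tract characteristics between inequality groups
#'
#' Tests each census covariate for a difference between high- and
#' low-inequality tracts: continuous and percentage variables with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test, and the owner/renter
#' housing composition with a chi-squared test on the aggregated 2x2
#' occupancy table (percentages weighted by tract household counts).
#'
#' @param tracts Tract tibble with an `inequality_group` column.
#' @param variables Continuous/percentage columns to test with Mann-Whitney.
#'   Defaults to every numeric column other than identifiers, bin counts and
#'   the owner/renter pair.
#' @param occupancy Length-2 character vector naming the owner and renter
#'   percentage columns for the chi-squared test, or `NULL` to skip.
#' @param weight Column used to scale occupancy percentages to counts.
#' @return Tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, and a `degenerate` flag for variables constant
#'   in both groups (reported with `p_value = 1`).
#' @export
compare_tract_groups <- function(tracts, variables = NULL,
                                 occupancy = c("pct_owner", "pct_renter"),
                                 weight = "n_households") {
  stopifnot("inequality_group" %in% names(tracts))
  g <- tracts$inequality_group
  if (length(unique(g)) != 2) {
    stop("Both inequality groups must be non-empty.", call. = FALSE)
  }
  if (is.null(variables)) {
    skip <- c("tract_id", "inequality_group", grep("^bin_", names(tracts), value = TRUE),
              occupancy, weight)
    variables <- setdiff(names(tracts)[vapply(tracts, is.numeric, logical(1))], skip)
  }
  rows <- purrr::map_dfr(variables, function(v) {
    x <- tracts[[v]][g == "low"]
    y <- tracts[[v]][g == "high"]
    if (stats::sd(tracts[[v]]) == 0) {
      return(tibble::tibble(variable = v, test = "mann_whitney",
                            statistic = NA_real_, p_value = 1, degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    tibble::tibble(variable = v, test = "mann_whitney",
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   degenerate = FALSE)
  })
  if (!is.null(occupancy) && all(c(occupancy, weight) %in% names(tracts))) {
    w <- tracts[[weight]]
    tab <- rbind(
      c(sum(tracts[[occupancy[1]]][g == "low"] / 100 * w[g == "low"]),
        sum(tracts[[occupancy[2]]][g == "low"] / 100 * w[g == "low"])),
      c(sum(tracts[[occupancy[1]]][g == "high"] / 100 * w[g == "high"]),
        sum(tracts[[occupancy[2]]][g == "high"] / 100 * w[g == "high"]))
    )
    ct <- suppressWarnings(stats::chisq.test(round(tab), correct = FALSE))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      variable = "owner_vs_renter", test = "chi_squared",
      statistic = unname(ct$statistic), p_value = ct$p.value, degenerate = FALSE))
  }
  rows
}
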