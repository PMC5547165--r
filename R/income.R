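#' Income-to-needs ratio against a low-income cut-off table
#'
#' Divides household income by the size-specific low-income cut-off (LICO),
#' yielding a dimensionless ratio; values near or below 1 indicate a
#' household likely to spend a disproportionate share of income on
#' necessities. Household sizes above the largest tabulated size use the top
#' entry (the conventional "7+" row).
#'
#' @param income Household income (currency units), `>= 0`. Vectorized.
#' @param size Household size, integer `>= 1`. Vectorized.
#' @param lico Data frame with columns `household_size` (1..max, no gaps)
#'   and `cutoff` (strictly increasing in size).
#' @return Numeric vector `income / cutoff[size]`.
#' @export
income_to_needs <- function(income, size, lico) {
  check_lico(lico)
  if (any(income < 0, na.rm = TRUE)) stop("Income must be non-negative.", call. = FALSE)
  if (any(size < 1, na.rm = TRUE)) stop("Household size must be >= 1.", call. = FALSE)
  sizes <- lico$household_size
  idx <- match(pmin(size, max(sizes)), sizes)
  if (any(is.na(idx) & !is.na(size))) {
    stop("LICO table is missing a household size below its maximum.", call. = FALSE)
  }
  income / lico$cutoff[idx]
}

check_lico <- function(lico) {
  stopifnot(all(c("household_size", "cutoff") %in% names(lico)))
  lico <- lico[order(lico$household_size), ]
  if (!all(diff(lico$household_size) == 1)) {
    stop("LICO table must tabulate consecutive household sizes.", call. = FALSE)
  }
  if (any(diff(lico$cutoff) <= 0)) {
    stop("LICO cut-offs must be strictly increasing in household size.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default (synthetic) low-income cut-off table
#'
#' A plausible before-tax LICO-style table for household sizes 1-7; the
#' actual cut-offs are configuration and should be supplied for real
#' analyses. Values are synthetic.
#'
#' @return Tibble with `household_size` and `cutoff` columns.
#' @export
default_lico <- function() {
  tibble::tibble(
    household_size = 1:7,
    cutoff = c(17900, 22300, 27400, 33200, 37700, 42500, 47400)
  )
}

#' Assign income groups and income-by-inequality subgroups
#'
#' Computes each adolescent's income-to-needs ratio, median-splits it
#' (ties-to-low) into low/high income groups, inherits the tract-level
#' inequality group, and crosses the two into one of four subgroup labels
#' per sex. The median split is pooled across sexes by default.
#'
#' Participants with missing household income or size are excluded before
#' the split, and the exclusions (with machine-readable reason codes) are
#' attached as the `"exclusions"` attribute. A non-missing `tract_id` absent
#' from the tract table is an error.
#'
#' @param cohort Cohort tibble with `participant_id`, `tract_id`, `sex`,
#'   `household_income`, `household_size` columns.
#' @param tracts Tract tibble with `tract_id` and `inequality_group`.
#' @param lico LICO table (see [income_to_needs()]); default [default_lico()].
#' @param split `"pooled"` (default) or `"by_sex"` median split.
#' @return Cohort tibble restricted to analyzable rows, with
#'   `income_to_needs`, `income_group`, `inequality_group` and `subgroup`
#'   columns; excluded rows recorded in `attr(., "exclusions")`.
#' @export
assign_subgroups <- function(cohort, tracts, lico = default_lico(),
                             split = c("pooled", "by_sex")) {
  split <- match.arg(split)
  stopifnot(all(c("participant_id", "tract_id", "household_income",
                  "household_size") %in% names(cohort)),
            all(c("tract_id", "inequality_group") %in% names(tracts)))
  cohort <- tibble::as_tibble(cohort)

  orphan <- !is.na(cohort$tract_id) & !(cohort$tract_id %in% tracts$tract_id)
  if (any(orphan)) {
    stop("tract_id values not present in tract table: ",
         paste(unique(cohort$tract_id[orphan]), collapse = ", "), call. = FALSE)
  }
  excl <- tibble::tibble(participant_id = cohort$participant_id,
                         reason = dplyr::case_when(
                           is.na(cohort$household_income) |
                             is.na(cohort$household_size) ~ "missing_income_or_size",
                           is.na(cohort$tract_id) ~ "missing_tract",
                           TRUE ~ NA_character_))
  excl <- excl[!is.na(excl$reason), ]
  keep <- cohort[!(cohort$participant_id %in% excl$participant_id), ]

  keep$income_to_needs <- income_to_needs(keep$household_income,
                                          keep$household_size, lico)
  keep$income_group <- if (split == "pooled") {
    median_split(keep$income_to_needs)
  } else {
    unsplit(lapply(split(keep$income_to_needs, keep$sex), median_split), keep$sex)
  }
  keep <- dplyr::left_join(keep,
                           dplyr::select(tracts, "tract_id", "inequality_group"),
                           by = "tract_id")
  keep$subgroup <- make_subgroup(keep$income_group, keep$inequality_group)
  attr(keep, "exclusions") <- excl
  keep
}

#' Subgroup label from income and inequality group
#'
#' @param income_group,inequality_group Character vectors of `"low"`/`"high"`.
#' @return Labels of the form `"low_income.high_ineq"`.
#' @export
make_subgroup <- function(income_group, inequality_group) {
  paste0(income_group, "_income.", inequality_group, "_ineq")
}

#' The four canonical subgroup labels
#' @return Character vector, low/high income crossed with high/low inequality.
#' @export
subgroup_levels <- function() {
  make_subgroup(rep(c("low", "high"), each = 2), rep(c("high", "low"), 2))
}
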