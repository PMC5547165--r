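#' The 34 Desikan-Killiany cortical region labels
#'
#' Standard FreeSurfer parcellation labels (left/right averaged upstream,
#' so one entry per region).
#'
#' @return Character vector of length 34.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' Simulation configuration for the synthetic study
#'
#' Assembles and validates every knob of the synthetic-cohort generator.
#' Defaults emulate the study design the analysis assumes: 37 census
#' tracts with Gini coefficients spanning 0.34-0.56, ~323 families per sex
#' with a 25% sibling rate (expected ~404 adolescents per sex), ages
#' uniform on 144-216 months, and per-subgroup linear thinning slopes
#' derived from target thickness-age R-squared values (female quartet
#' 0.255/0.050/0.017/0.14 for low-high/low-low/high-high/high-low
#' income-inequality cells; males ~0.31 throughout). Expression-association
#' coefficients are derived analogously from target per-subgroup profile
#' R-squared values (NR3C1 female quartet 0.41/0.003/0.18/0.36; males
#' 0.45/0.38/0.30/0.33).
#'
#' Slopes are obtained from a target R-squared by
#' `slope = -sqrt(R2/(1-R2) * Vn/Va)` where `Va` is the age variance and
#' `Vn = residual_sd^2 + family_sd^2`; association coefficients (mm/month
#' of extra thinning per SD of regional expression) from the target profile
#' R-squared given the per-region sampling noise of a Fisher z at the
#' expected subgroup size.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_tracts Number of census tracts (default 37).
#' @param n_families Families per sex (default 323).
#' @param sibling_rate Fraction of families contributing 2 adolescents.
#' @param age_range_months Low/high bounds of the uniform age distribution.
#' @param bin_edges 12 strictly increasing boundaries for the 11 census
#'   income bins; last may be `Inf`.
#' @param gini_range Range spanned (evenly) by the true tract Ginis.
#' @param mean_income Typical tract mean household income (currency).
#' @param mean_income_sdlog Lognormal spread of tract mean incomes.
#' @param population_range Tract population bounds (persons).
#' @param persons_per_household Used to convert population to households.
#' @param baseline_thickness Mean cortical thickness at the age midpoint (mm).
#' @param residual_sd Within-person residual SD of thickness (mm).
#' @param family_sd SD of the shared family intercept (mm).
#' @param region_sd SD of fixed regional baseline offsets (mm).
#' @param subgroup_r2 Named list (`F`, `M`) of per-subgroup target
#'   thickness-age R-squared values used to derive `subgroup_slopes`.
#' @param subgroup_slopes Optional named list (`F`, `M`) of per-subgroup
#'   slopes (mm/month) overriding the R-squared-derived defaults.
#' @param profile_r2 Named list (`F`, `M`) of per-subgroup target
#'   expression-profile R-squared values used to derive `expr_association`.
#' @param expr_association Optional named list (`F`, `M`) of per-subgroup
#'   association coefficients (mm/month per SD expression) overriding the
#'   derived defaults; 0 disables the regional expression signal.
#' @param expression_correlation Target inter-gene Pearson r across regions.
#' @param n_regions Number of cortical regions (default 34, must be >= 3).
#' @param income_sdlog Lognormal spread of household income within a tract.
#' @param household_size_probs Probabilities for household sizes 2-7.
#' @param lico Low-income cut-off table (see [income_to_needs()]).
#' @return A validated list of class `ng_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tracts = 37L,
                       n_families = 323L,
                       sibling_rate = 0.25,
                       age_range_months = c(144, 216),
                       bin_edges = c(seq(0, 1e5, by = 1e4), Inf),
                       gini_range = c(0.34, 0.56),
                       mean_income = 55000,
                       mean_income_sdlog = 0.12,
                       population_range = c(2500, 8000),
                       persons_per_household = 2.4,
                       baseline_thickness = 3.10,
                       residual_sd = 0.12,
                       family_sd = 0.05,
                       region_sd = 0.35,
                       subgroup_r2 = NULL,
                       subgroup_slopes = NULL,
                       profile_r2 = NULL,
                       expr_association = NULL,
                       expression_correlation = 0.75,
                       n_regions = 34L,
                       income_sdlog = 0.45,
                       household_size_probs = c(0.06, 0.18, 0.38, 0.25, 0.09, 0.04),
                       lico = default_lico()) {
  if (any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing.", call. = FALSE)
  }
  if (n_regions < 3) stop("`n_regions` must be >= 3.", call. = FALSE)
  if (abs(expression_correlation) >= 1) {
    stop("|expression_correlation| must be < 1.", call. = FALSE)
  }
  stopifnot(residual_sd >= 0, family_sd >= 0, region_sd >= 0,
            sibling_rate >= 0, sibling_rate <= 1,
            age_range_months[1] < age_range_months[2],
            length(household_size_probs) == 6)
  check_lico(lico)

  sg <- subgroup_levels() # low.high, low.low, high.high, high.low
  if (is.null(subgroup_r2)) {
    subgroup_r2 <- list(
      F = stats::setNames(c(0.255, 0.050, 0.017, 0.14), sg),
      M = stats::setNames(rep(0.31, 4), sg))
  }
  if (is.null(profile_r2)) {
    profile_r2 <- list(
      F = stats::setNames(c(0.41, 0.003, 0.18, 0.36), sg),
      M = stats::setNames(c(0.45, 0.38, 0.30, 0.33), sg))
  }
  age_var <- diff(age_range_months)^2 / 12
  noise_var <- residual_sd^2 + family_sd^2
  if (is.null(subgroup_slopes)) {
    subgroup_slopes <- lapply(subgroup_r2, function(r2) {
      -sqrt(r2 / (1 - r2) * noise_var / age_var)
    })
  }
  if (is.null(expr_association)) {
    n_sub <- n_families * (1 + sibling_rate) / 4
    sigma_z <- 1 / sqrt(n_sub - 3)
    expr_association <- lapply(names(profile_r2), function(sex) {
      beta_z <- -sqrt(profile_r2[[sex]] / (1 - profile_r2[[sex]])) * sigma_z
      tot <- subgroup_slopes[[sex]][names(beta_z)]^2 * age_var + noise_var
      beta_z * sqrt(tot) / sqrt(age_var)
    })
    names(expr_association) <- names(profile_r2)
  }
  structure(list(
    seed = as.integer(seed), n_tracts = as.integer(n_tracts),
    n_families = as.integer(n_families), sibling_rate = sibling_rate,
    age_range_months = age_range_months, bin_edges = bin_edges,
    gini_range = gini_range, mean_income = mean_income,
    mean_income_sdlog = mean_income_sdlog,
    population_range = population_range,
    persons_per_household = persons_per_household,
    baseline_thickness = baseline_thickness, residual_sd = residual_sd,
    family_sd = family_sd, region_sd = region_sd,
    subgroup_r2 = subgroup_r2, subgroup_slopes = subgroup_slopes,
    profile_r2 = profile_r2, expr_association = expr_association,
    expression_correlation = expression_correlation,
    n_regions = as.integer(n_regions), income_sdlog = income_sdlog,
    household_size_probs = household_size_probs, lico = lico
  ), class = "ng_sim_config")
}

#' Generate synthetic census tracts with known Gini coefficients
#'
#' Draws, for each tract, a lognormal household-income sample whose scale
#' parameter is set from an evenly spaced target Gini via
#' `sigma = sqrt(2) * qnorm((G+1)/2)` (the closed-form lognormal Gini
#' inverted), records the exact microdata Gini of the sample as ground
#' truth, bins the sample into the 11 census bins, and attaches Table-1
#' style census covariates (population density, housing percentages,
#' education, owner/renter shares) with realistic dependence on
#' inequality.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per tract: `tract_id`, `population`,
#'   `n_households`, `mean_income`, `gini_true`, `bin_1`..`bin_11`, and
#'   census covariates.
#' @export
generate_tracts <- function(config) {
  stopifnot(inherits(config, "ng_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_tracts
    g_target <- seq(config$gini_range[1], config$gini_range[2], length.out = n)
    sigma <- sqrt(2) * stats::qnorm((g_target + 1) / 2)
    mean_inc <- stats::rlnorm(n, log(config$mean_income) -
                                config$mean_income_sdlog^2 / 2,
                              config$mean_income_sdlog)
    population <- round(stats::runif(n, config$population_range[1],
                                     config$population_range[2]))
    n_households <- pmax(round(population / config$persons_per_household), 50L)
    edges <- config$bin_edges
    k <- length(edges) - 1L
    bins <- matrix(0L, n, k)
    gini_true <- numeric(n)
    sample_mean <- numeric(n)
    for (i in seq_len(n)) {
      x <- stats::rlnorm(n_households[i],
                         log(mean_inc[i]) - sigma[i]^2 / 2, sigma[i])
      gini_true[i] <- gini_exact(x)
      sample_mean[i] <- mean(x)
      bins[i, ] <- tabulate(findInterval(x, edges), nbins = k)
    }
    gbar <- mean(g_target)
    covar <- tibble::tibble(
      pop_density = exp(stats::rnorm(n, 6.6 + 8 * (g_target - gbar), 0.4)),
      pct_single_detached = 100 * stats::plogis(
        stats::qlogis(0.55) - 10 * (g_target - gbar) + stats::rnorm(n, 0, 0.3)),
      pct_apartment = 100 * stats::plogis(
        stats::qlogis(0.18) + 10 * (g_target - gbar) + stats::rnorm(n, 0, 0.3)),
      pct_no_highschool = stats::runif(n, 10, 20),
      pct_university = 100 * stats::plogis(
        stats::qlogis(0.20) + 2 * (g_target - gbar) + stats::rnorm(n, 0, 0.2)),
      pct_owner = 100 * stats::plogis(
        stats::qlogis(0.65) - 10 * (g_target - gbar) + stats::rnorm(n, 0, 0.3))
    )
    covar$pct_renter <- 100 - covar$pct_owner
    out <- tibble::tibble(
      tract_id = sprintf("T%02d", seq_len(n)),
      population = population, n_households = n_households,
      mean_income = sample_mean, gini_true = gini_true)
    binned <- tibble::as_tibble(as.data.frame(bins))
    names(binned) <- paste0("bin_", seq_len(k))
    dplyr::bind_cols(out, binned, covar)
  })
}

#' Generate correlated NR3C1 and AR expression profiles
#'
#' Produces two expression vectors over the cortical regions whose sample
#' Pearson correlation hits the configured target. The default `"exact"`
#' method builds the second vector from an empirically orthogonalized basis
#' (a Cholesky-style construction), so the realized sample correlation
#' equals the target exactly; `"sample"` draws from a bivariate normal and
#' resamples until the realized correlation is within `tol` of the target.
#'
#' @param config A [sim_config()].
#' @param method `"exact"` (default) or `"sample"`.
#' @param tol Acceptance window for `"sample"` (default 0.08).
#' @param max_tries Bounded retries for `"sample"` before erroring.
#' @return Tibble with `region`, `expr_NR3C1`, `expr_AR`.
#' @export
generate_expression <- function(config, method = c("exact", "sample"),
                                tol = 0.08, max_tries = 1000L) {
  stopifnot(inherits(config, "ng_sim_config"))
  method <- match.arg(method)
  rho <- config$expression_correlation
  n <- config$n_regions
  withr::with_seed(config$seed + 1L, {
    if (method == "exact") {
      x0 <- stats::rnorm(n)
      y0 <- stats::rnorm(n)
      x <- as.numeric(scale(x0))
      e <- stats::resid(stats::lm(y0 ~ x0))
      y <- rho * x + sqrt(1 - rho^2) * as.numeric(scale(e))
    } else {
      ok <- FALSE
      for (i in seq_len(max_tries)) {
        x <- stats::rnorm(n)
        y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
        if (abs(stats::cor(x, y) - rho) <= tol) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("Could not reach the target correlation within ", max_tries,
             " resamples.", call. = FALSE)
      }
      x <- as.numeric(scale(x))
      y <- as.numeric(scale(y))
    }
    regions <- if (n <= 34) dk_regions()[seq_len(n)] else {
      c(dk_regions(), sprintf("region_%02d", 35:n))
    }
    tibble::tibble(region = regions,
                   expr_NR3C1 = 7.5 + 0.6 * x,
                   expr_AR = 5.5 + 0.5 * y)
  })
}

#' Generate a family-nested synthetic cohort with known ground truth
#'
#' Families (per sex) are assigned to tracts with probability proportional
#' to population; each contributes one adolescent, or two with probability
#' `sibling_rate`, sharing a household income, size and family intercept.
#' Ages are uniform on the configured range. Mean cortical thickness is
#' `baseline + family intercept + slope * (age - midpoint) + noise`, with
#' the slope keyed by the participant's true (income, inequality, sex)
#' subgroup. Regional thickness adds fixed region baselines and a
#' region-specific slope `slope + gamma * x_region`, where `x_region` is
#' the standardized NR3C1 expression of the region and `gamma` the
#' configured per-subgroup association coefficient.
#'
#' True income groups come from a pooled ties-to-low median split of the
#' generated income-to-needs ratios; true inequality groups from
#' residualizing the exact tract Ginis on tract mean income and median
#' splitting, i.e. the same rules the analysis modules apply.
#'
#' @param config A [sim_config()].
#' @param tracts Output of [generate_tracts()] (non-empty).
#' @param expression Output of [generate_expression()]; regenerated from
#'   `config` when `NULL`.
#' @return List with `cohort` (tibble, one row per adolescent) and `truth`
#'   (list: `subgroup_slopes`, `expr_association`, `tract_truth`,
#'   `participant_truth`).
#' @export
generate_cohort <- function(config, tracts, expression = NULL) {
  stopifnot(inherits(config, "ng_sim_config"))
  if (is.null(tracts) || nrow(tracts) == 0) {
    stop("Tract table must be non-empty.", call. = FALSE)
  }
  if (is.null(expression)) expression <- generate_expression(config)
  tr <- residualize_gini(
    dplyr::mutate(tracts, gini = .data$gini_true))
  tr$inequality_group <- median_split(tr$gini_residual)

  withr::with_seed(config$seed + 2L, {
    mid <- mean(config$age_range_months)
    x_expr <- as.numeric(scale(expression$expr_NR3C1))
    region_base <- config$baseline_thickness +
      stats::rnorm(config$n_regions, 0, config$region_sd)

    fam <- purrr::map_dfr(c("F", "M"), function(sex) {
      nf <- config$n_families
      tibble::tibble(
        sex = sex,
        family_id = sprintf("fam_%s_%03d", sex, seq_len(nf)),
        tract_id = sample(tr$tract_id, nf, replace = TRUE,
                          prob = tr$population),
        household_size = sample(2:7, nf, replace = TRUE,
                                prob = config$household_size_probs),
        n_children = 1L + stats::rbinom(nf, 1L, config$sibling_rate),
        b_f = stats::rnorm(nf, 0, config$family_sd)
      )
    })
    fam <- dplyr::left_join(fam,
                            dplyr::select(tr, "tract_id", "mean_income",
                                          tract_ineq = "inequality_group"),
                            by = "tract_id")
    fam$household_income <- stats::rlnorm(
      nrow(fam), log(fam$mean_income) - config$income_sdlog^2 / 2,
      config$income_sdlog)

    kids <- fam[rep(seq_len(nrow(fam)), fam$n_children), ]
    kids$participant_id <- sprintf("P%04d", seq_len(nrow(kids)))
    kids$age_months <- stats::runif(nrow(kids), config$age_range_months[1],
                                    config$age_range_months[2])
    kids$income_to_needs <- income_to_needs(kids$household_income,
                                            kids$household_size, config$lico)
    kids$income_group <- median_split(kids$income_to_needs)
    kids$subgroup <- make_subgroup(kids$income_group, kids$tract_ineq)

    slope <- purrr::map2_dbl(kids$sex, kids$subgroup, function(s, g) {
      config$subgroup_slopes[[s]][[g]]
    })
    gamma <- purrr::map2_dbl(kids$sex, kids$subgroup, function(s, g) {
      config$expr_association[[s]][[g]]
    })
    age_d <- kids$age_months - mid
    nk <- nrow(kids)
    kids$mean_thickness <- config$baseline_thickness + kids$b_f +
      slope * age_d + stats::rnorm(nk, 0, config$residual_sd)

    thk <- matrix(0, nk, config$n_regions)
    for (j in seq_len(config$n_regions)) {
      thk[, j] <- region_base[j] + kids$b_f +
        (slope + gamma * x_expr[j]) * age_d +
        stats::rnorm(nk, 0, config$residual_sd)
    }
    colnames(thk) <- paste0("thk_", expression$region)

    kids$parental_education <- sample(1:9, nk, replace = TRUE,
      prob = c(0.01, 0.03, 0.08, 0.18, 0.22, 0.20, 0.14, 0.09, 0.05))
    kids$maternal_smoking <- stats::rbinom(nk, 1, 0.22) == 1

    cohort <- dplyr::bind_cols(
      dplyr::select(kids, "participant_id", "family_id", "tract_id", "sex",
                    "age_months", "household_income", "household_size",
                    "parental_education", "maternal_smoking",
                    "mean_thickness"),
      tibble::as_tibble(as.data.frame(thk)))

    truth <- list(
      subgroup_slopes = config$subgroup_slopes,
      expr_association = config$expr_association,
      tract_truth = dplyr::select(tr, "tract_id", "gini_true",
                                  "gini_residual", "inequality_group"),
      participant_truth = dplyr::select(kids, "participant_id",
                                        "income_to_needs", "income_group",
                                        inequality_group = "tract_ineq",
                                        "subgroup")
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Write the full synthetic study to disk
#'
#' Generates tracts, expression and cohort tables under one configuration
#' and writes them as UTF-8 comma-separated files with header rows, plus a
#' JSON sidecar holding the ground truth and a copy of the LICO table.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tracts <- generate_tracts(config)
  expression <- generate_expression(config)
  gen <- generate_cohort(config, tracts, expression)
  paths <- list(
    tracts = file.path(dir, "tracts.csv"),
    cohort = file.path(dir, "cohort.csv"),
    expression = file.path(dir, "expression.csv"),
    lico = file.path(dir, "lico.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(tracts, paths$tracts)
  readr::write_csv(gen$cohort, paths$cohort)
  readr::write_csv(expression, paths$expression)
  readr::write_csv(config$lico, paths$lico)
  truth <- gen$truth
  truth$subgroup_slopes <- lapply(truth$subgroup_slopes, as.list)
  truth$expr_association <- lapply(truth$expr_association, as.list)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
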