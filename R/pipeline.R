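#' Configuration of a full pipeline run
#'
#' Collects everything a run needs: either a simulation configuration or
#' paths to the three input CSVs (plus a LICO table), the strata and genes
#' to analyse, the Gini method, the FDR level, adjustment flags, output
#' directory and seed. A YAML file with these fields can be loaded with
#' [read_run_config()].
#'
#' @param simulate Generate inputs synthetically (default) or read CSVs.
#' @param sim A [sim_config()]; used when `simulate = TRUE`. Defaults to
#'   `sim_config(seed = seed)`.
#' @param tracts_csv,cohort_csv,expression_csv,lico_csv Input paths,
#'   required when `simulate = FALSE` (`lico_csv` optional; falls back to
#'   [default_lico()]).
#' @param bin_edges Income-bin boundaries for the tract table.
#' @param sexes Sex strata to run.
#' @param genes Genes to test.
#' @param gini_method Passed to [assign_inequality()].
#' @param fdr_alpha FDR level in `(0, 1)`.
#' @param adjust_covariates Adjust thickness for parental education and
#'   maternal smoking before modelling.
#' @param include_age2 Add the age-squared terms in the three-way model.
#' @param df Denominator df convention for all tests.
#' @param out_dir Directory for result CSVs and the manifest; `NULL` keeps
#'   results in memory only.
#' @param make_figures Also write thickness-age and profile figures.
#' @param seed Seed for the simulation path.
#' @return A validated list of class `ng_run_config`.
#' @export
run_config <- function(simulate = TRUE, sim = NULL,
                       tracts_csv = NULL, cohort_csv = NULL,
                       expression_csv = NULL, lico_csv = NULL,
                       bin_edges = c(seq(0, 1e5, by = 1e4), Inf),
                       sexes = c("F", "M"), genes = c("NR3C1", "AR"),
                       gini_method = c("lognormal_mle", "midpoint"),
                       fdr_alpha = 0.05, adjust_covariates = FALSE,
                       include_age2 = FALSE,
                       df = c("residual", "printed"),
                       out_dir = NULL, make_figures = FALSE, seed = 1L) {
  gini_method <- match.arg(gini_method)
  df <- match.arg(df)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop("`fdr_alpha` must be in (0, 1).", call. = FALSE)
  }
  if (simulate) {
    if (is.null(sim)) sim <- sim_config(seed = seed)
    bin_edges <- sim$bin_edges
  } else {
    paths <- c(tracts = tracts_csv, cohort = cohort_csv,
               expression = expression_csv)
    if (length(paths) < 3 || any(!file.exists(paths))) {
      stop("With `simulate = FALSE`, tracts_csv, cohort_csv and ",
           "expression_csv must exist.", call. = FALSE)
    }
  }
  structure(list(
    simulate = simulate, sim = sim, tracts_csv = tracts_csv,
    cohort_csv = cohort_csv, expression_csv = expression_csv,
    lico_csv = lico_csv, bin_edges = bin_edges, sexes = sexes,
    genes = genes, gini_method = gini_method, fdr_alpha = fdr_alpha,
    adjust_covariates = adjust_covariates, include_age2 = include_age2,
    df = df, out_dir = out_dir, make_figures = make_figures,
    seed = as.integer(seed)
  ), class = "ng_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level fields map to [run_config()] arguments; a nested `sim` block
#' maps to [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return An `ng_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

#' Validate input tables against the expected schemas
#'
#' Checks column presence (header-keyed, order-free), basic types, 34
#' unique region labels in the expression table and matching `thk_*`
#' columns in the cohort, non-negative bin counts, and an increasing LICO
#' table. Failures are reported, not raised.
#'
#' @param paths Named list/vector with any of `tracts`, `cohort`,
#'   `expression`, `lico` paths.
#' @return Tibble with `file`, `check`, `ok`, `detail` rows.
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  note <- function(file, check, ok, detail = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      file = file, check = check, ok = ok, detail = detail)
  }
  read1 <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                       progress = FALSE)
  if (!is.null(paths$tracts)) {
    if (!file.exists(paths$tracts)) {
      note("tracts", "exists", FALSE, paths$tracts)
    } else {
      d <- read1(paths$tracts)
      need <- c("tract_id", "mean_income", "population")
      miss <- setdiff(need, names(d))
      note("tracts", "columns", length(miss) == 0, paste(miss, collapse = ", "))
      bins <- grep("^bin_", names(d), value = TRUE)
      note("tracts", "eleven_bins", length(bins) == 11,
           paste(length(bins), "bin columns"))
      if (length(bins) > 0) {
        neg <- any(as.matrix(d[, bins]) < 0)
        note("tracts", "counts_nonnegative", !neg)
      }
    }
  }
  if (!is.null(paths$cohort)) {
    if (!file.exists(paths$cohort)) {
      note("cohort", "exists", FALSE, paths$cohort)
    } else {
      d <- read1(paths$cohort)
      need <- c("participant_id", "family_id", "tract_id", "sex",
                "age_months", "household_income", "household_size",
                "mean_thickness")
      miss <- setdiff(need, names(d))
      note("cohort", "columns", length(miss) == 0, paste(miss, collapse = ", "))
      thk <- sub("^thk_", "", grep("^thk_", names(d), value = TRUE))
      missing_regions <- setdiff(dk_regions(), thk)
      note("cohort", "regions_34",
           length(thk) == 34 && length(missing_regions) == 0,
           if (length(missing_regions) > 0)
             paste("missing:", paste(missing_regions, collapse = ", "))
           else paste(length(thk), "regions"))
    }
  }
  if (!is.null(paths$expression)) {
    if (!file.exists(paths$expression)) {
      note("expression", "exists", FALSE, paths$expression)
    } else {
      d <- read1(paths$expression)
      miss <- setdiff(c("region", "expr_NR3C1", "expr_AR"), names(d))
      note("expression", "columns", length(miss) == 0,
           paste(miss, collapse = ", "))
      if ("region" %in% names(d)) {
        missing_regions <- setdiff(dk_regions(), d$region)
        note("expression", "regions_34",
           length(unique(d$region)) == 34 && length(missing_regions) == 0,
           if (length(missing_regions) > 0)
             paste("missing:", paste(missing_regions, collapse = ", "))
           else "34 unique regions")
      }
    }
  }
  if (!is.null(paths$lico)) {
    if (!file.exists(paths$lico)) {
      note("lico", "exists", FALSE, paths$lico)
    } else {
      d <- read1(paths$lico)
      ok <- tryCatch({ check_lico(d); TRUE }, error = function(e) FALSE)
      note("lico", "valid", ok)
    }
  }
  dplyr::bind_rows(rows)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes inequality grouping, income grouping, the family-nested
#' thickness models (three-way interaction, within-income follow-ups,
#' subgroup slopes, pairwise contrasts) and the expression-profile
#' regressions, end-to-end, on synthetic or user-supplied inputs. FDR
#' adjustment is applied within each declared family (thickness
#' interactions per sex; profile interactions per gene and sex). When
#' `out_dir` is set, tidy CSVs, the exclusion log and a machine-readable
#' manifest (seed, versions, file hashes) are written; identical config and
#' seed produce an identical manifest hash.
#'
#' @param config An [run_config()].
#' @return A result bundle (list): `tracts`, `cohort`, `exclusions`,
#'   `thickness_tests`, `slopes`, `slope_contrasts`, `profiles`,
#'   `profile_tests`, `profile_fits`, `gene_correlation`, `manifest`, and
#'   `truth` for simulated runs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ng_run_config"))
  inputs <- stage("inputs", {
    if (config$simulate) {
      tracts <- generate_tracts(config$sim)
      expression <- generate_expression(config$sim)
      gen <- generate_cohort(config$sim, tracts, expression)
      lico <- config$sim$lico
      list(tracts = tracts, cohort = gen$cohort, expression = expression,
           lico = lico, truth = gen$truth)
    } else {
      lico <- if (!is.null(config$lico_csv)) {
        readr::read_csv(config$lico_csv, show_col_types = FALSE)
      } else default_lico()
      list(
        tracts = readr::read_csv(config$tracts_csv, show_col_types = FALSE),
        cohort = readr::read_csv(config$cohort_csv, show_col_types = FALSE),
        expression = readr::read_csv(config$expression_csv,
                                     show_col_types = FALSE),
        lico = lico, truth = NULL)
    }
  })

  tracts <- stage("inequality", {
    assign_inequality(inputs$tracts, config$bin_edges,
                      method = config$gini_method)
  })
  cohort <- stage("income_grouping", {
    assign_subgroups(inputs$cohort, tracts, lico = inputs$lico)
  })
  exclusions <- attr(cohort, "exclusions")
  if (config$adjust_covariates) {
    cohort <- stage("adjustment", adjust_thickness(cohort))
  }

  thickness <- stage("cohort_models", {
    tests <- purrr::map_dfr(config$sexes, function(sx) {
      res <- list(
        fit_three_way(cohort, sx, include_age2 = config$include_age2,
                      df = config$df),
        fit_age_by_inequality(cohort, sx, "low", df = config$df),
        fit_age_by_inequality(cohort, sx, "high", df = config$df))
      out <- fdr_adjust(res, alpha = config$fdr_alpha)
      out$sex <- sx
      out
    })
    slopes <- purrr::map_dfr(config$sexes, function(sx) {
      s <- subgroup_slopes(cohort, sex = sx); s$sex <- sx; s
    })
    contrasts <- purrr::map_dfr(config$sexes, function(sx) {
      s <- compare_all_slopes(cohort, sex = sx); s$sex <- sx; s
    })
    list(tests = tests, slopes = slopes, contrasts = contrasts)
  })

  profs <- stage("expression_profile", {
    profiles <- build_region_profiles(cohort, inputs$expression)
    tests <- purrr::map_dfr(config$sexes, function(sx) {
      purrr::map_dfr(config$genes, function(gene) {
        res <- list(
          fit_profile_three_way(profiles, gene, sx, df = config$df),
          fit_profile_within_income(profiles, gene, sx, "low", df = config$df),
          fit_profile_within_income(profiles, gene, sx, "high", df = config$df))
        out <- fdr_adjust(res, alpha = config$fdr_alpha)
        out$sex <- sx
        out
      })
    })
    fits <- purrr::map_dfr(config$sexes, function(sx) {
      purrr::map_dfr(config$genes, function(gene) {
        f <- subgroup_profile_fits(profiles, gene, sex = sx)
        f$gene <- gene; f$sex <- sx; f
      })
    })
    list(profiles = profiles, tests = tests, fits = fits,
         gene_correlation = expression_gene_correlation(inputs$expression))
  })

  bundle <- list(
    tracts = tracts, cohort = cohort, exclusions = exclusions,
    thickness_tests = thickness$tests, slopes = thickness$slopes,
    slope_contrasts = thickness$contrasts, profiles = profs$profiles,
    profile_tests = profs$tests, profile_fits = profs$fits,
    gene_correlation = profs$gene_correlation, truth = inputs$truth)

  if (!is.null(config$out_dir)) {
    bundle$manifest <- stage("reporting", {
      write_bundle(bundle, config)
    })
  }
  bundle
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("tracts", "thickness_tests", "slopes", "slope_contrasts",
             "profiles", "profile_tests", "profile_fits",
             "gene_correlation", "exclusions")
  paths <- character(0)
  for (f in files) {
    p <- file.path(config$out_dir, paste0(f, ".csv"))
    readr::write_csv(tibble::as_tibble(bundle[[f]]), p)
    paths[f] <- p
  }
  if (isTRUE(config$make_figures)) {
    for (sx in config$sexes) {
      ggplot2::ggsave(file.path(config$out_dir,
                                paste0("thickness_age_", sx, ".png")),
                      plot_thickness_age(bundle$cohort, sex = sx),
                      width = 8, height = 4, dpi = 150)
      for (gene in config$genes) {
        ggplot2::ggsave(
          file.path(config$out_dir, paste0("profile_", gene, "_", sx, ".png")),
          plot_profile_association(bundle$profiles, gene, sex = sx),
          width = 8, height = 4, dpi = 150)
      }
    }
  }
  hashes <- tools::md5sum(paths)
  names(hashes) <- names(paths)
  manifest <- list(
    seed = config$seed,
    simulate = config$simulate,
    gini_method = config$gini_method,
    fdr_alpha = config$fdr_alpha,
    df = config$df,
    package_version = as.character(utils::packageVersion("neurogini")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    file_md5 = as.list(hashes)
  )
  combined <- tempfile()
  writeLines(unlist(hashes), combined)
  manifest$manifest_hash <- unname(tools::md5sum(combined))
  unlink(combined)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
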