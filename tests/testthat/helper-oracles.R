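# Independent oracles and small fixture builders shared across tests.

# Mean-normalized pairwise absolute-difference Gini: the textbook definition,
# independent of the Lorenz-polyline implementation it checks.
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# OLS residuals by explicit normal equations (independent of stats::lm).
ols_residuals <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Exact two-sided Mann-Whitney p-value by enumerating all assignments of
# ranks to the first group (small n only).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(a) {
    xs <- pooled[a]
    ys <- pooled[-a]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  m <- n1 * length(y) / 2
  # two-sided: double the smaller tail (as the exact rank-sum test does)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# A small, fast simulation configuration for property tests.
small_config <- function(seed = 1L, n_families = 60L, ...) {
  sim_config(seed = seed, n_tracts = 8L, n_families = n_families,
             population_range = c(2500, 3500), ...)
}

# Tiny cohort with explicit group labels for model-level unit tests.
toy_cohort <- function(n_per_cell = 30, seed = 42, slope = -0.002,
                       noise = 0.08, sibling = FALSE) {
  withr::with_seed(seed, {
    cells <- expand.grid(income_group = c("low", "high"),
                         inequality_group = c("low", "high"),
                         stringsAsFactors = FALSE)
    d <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(income_group = cells$income_group[i],
                 inequality_group = cells$inequality_group[i],
                 age_months = runif(n_per_cell, 144, 216))
    }))
    n <- nrow(d)
    d$sex <- "F"
    d$participant_id <- sprintf("P%03d", seq_len(n))
    d$family_id <- if (sibling) sprintf("fam%03d", rep(seq_len(n / 2), each = 2))
                   else sprintf("fam%03d", seq_len(n))
    d$subgroup <- make_subgroup(d$income_group, d$inequality_group)
    d$mean_thickness <- 3.1 + slope * (d$age_months - 180) + rnorm(n, 0, noise)
    tibble::as_tibble(d)
  })
}
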