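#' Thickness-by-age scatter with per-inequality-group fit lines
#'
#' One panel per income group; high-inequality participants drawn with
#' solid points and a solid fit line, low-inequality with hollow points and
#' a dashed line.
#'
#' @param cohort Cohort tibble with `subgroup` assignments.
#' @param sex Optional sex filter.
#' @return A ggplot object.
#' @export
plot_thickness_age <- function(cohort, sex = NULL) {
  d <- tibble::as_tibble(cohort)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_months,
                                  y = .data$mean_thickness,
                                  linetype = .data$inequality_group,
                                  shape = .data$inequality_group)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "black") +
    ggplot2::facet_wrap(~income_group,
                        labeller = ggplot2::labeller(
                          income_group = c(low = "Low income",
                                           high = "High income"))) +
    ggplot2::scale_linetype_manual(values = c(low = "dashed", high = "solid")) +
    ggplot2::scale_shape_manual(values = c(low = 1, high = 16)) +
    ggplot2::labs(x = "Age (months)", y = "Mean cortical thickness (mm)",
                  linetype = "Inequality", shape = "Inequality") +
    ggplot2::theme_minimal()
}

#' Fisher z profile versus gene expression, per inequality group
#'
#' The 34 regional thickness-age Fisher z values plotted against the gene's
#' regional expression, one panel per income group, with per-inequality
#' fit lines.
#'
#' @param profiles Output of [build_region_profiles()].
#' @param gene `"NR3C1"` or `"AR"`.
#' @param sex Optional sex filter.
#' @return A ggplot object.
#' @export
plot_profile_association <- function(profiles, gene, sex = NULL) {
  d <- tibble::as_tibble(profiles)
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  d$expr <- d[[paste0("expr_", gene)]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expr, y = .data$z,
                                  linetype = .data$inequality_group,
                                  shape = .data$inequality_group)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "black") +
    ggplot2::facet_wrap(~income_group,
                        labeller = ggplot2::labeller(
                          income_group = c(low = "Low income",
                                           high = "High income"))) +
    ggplot2::scale_linetype_manual(values = c(low = "dashed", high = "solid")) +
    ggplot2::scale_shape_manual(values = c(low = 1, high = 16)) +
    ggplot2::labs(x = paste(gene, "expression (atlas units)"),
                  y = "Thickness-age correlation (Fisher z)",
                  linetype = "Inequality", shape = "Inequality") +
    ggplot2::theme_minimal()
}
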