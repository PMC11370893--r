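#' Plot per-species site profiles
#'
#' Scatter of detection frequency against mean relative abundance per body
#' site, one point per species and site — the two quantities the body-site
#' rule consumes. Abundance is shown on a log scale with an offset for zeros.
#'
#' @param profiles Output of [compute_site_profiles()].
#' @param abundance_offset Added to mean abundance before log scaling so
#'   absent species remain plottable.
#' @return A ggplot object.
#' @export
plot_site_profiles <- function(profiles, abundance_offset = 1e-6) {
  long <- profiles |>
    dplyr::select("species", dplyr::starts_with("f_"),
                  dplyr::starts_with("a_")) |>
    tidyr::pivot_longer(-"species",
                        names_to = c("measure", "site"), names_sep = "_") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$f,
                                     y = .data$a + abundance_offset,
                                     color = .data$site)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "detection frequency",
                  y = "mean relative abundance (log scale)",
                  color = "body site") +
    ggplot2::theme_minimal()
}

#' Plot a cross-study overlap histogram
#'
#' @param histogram Output of [study_overlap_histogram()].
#' @return A ggplot object (bar chart of species counts by number of
#'   reporting studies, labelled with percentages).
#' @export
plot_overlap_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(x = factor(.data$k),
                                          y = .data$n_species)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "number of meta-studies reporting the species",
                  y = "species") +
    ggplot2::theme_minimal()
}

#' Plot property proportions by direction class
#'
#' Bar chart of the [table1_summary()] percentages: share of species with
#' each property (bacteremia, aerotolerant, oral, extra-intestinal) among
#' enriched vs depleted species, faceted by disease-count group.
#'
#' @param summary Output of [table1_summary()].
#' @return A ggplot object.
#' @export
plot_table1_summary <- function(summary) {
  dat <- dplyr::filter(summary, .data$category != "total")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$percent,
                                    fill = .data$direction_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~.data$disease_group) +
    ggplot2::scale_fill_manual(values = c(enriched = "#d62728",
                                          depleted = "#1f77b4")) +
    ggplot2::labs(x = NULL, y = "% of signature species",
                  fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a comparison battery
#'
#' Odds ratios (conditional MLE, log scale) of every non-degenerate
#' comparison in a [run_comparison_battery()] result, annotated with the
#' exact p-values. Boundary odds ratios (0 or infinite) are drawn at the
#' panel edges with open symbols.
#'
#' @param object A `comparison_battery` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_battery
#' @export
autoplot.comparison_battery <- function(object, ...) {
  dat <- object |>
    dplyr::filter(!.data$degenerate) |>
    dplyr::mutate(
      boundary = !is.finite(.data$odds_ratio) | .data$odds_ratio == 0,
      or_plot = pmin(pmax(.data$odds_ratio, 1e-2), 1e2),
      comparison_id = factor(.data$comparison_id,
                             levels = rev(.data$comparison_id))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or_plot,
                                    y = .data$comparison_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$boundary,
                                     color = .data$p_value < 0.05),
                        size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d62728",
                                           `FALSE` = "grey40"),
                                name = "p < 0.05") +
    ggplot2::labs(x = "odds ratio (conditional MLE, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
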