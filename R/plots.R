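# ggplot2 displays for the main result types.

#' Plot an evolutionary rate fit
#'
#' Maintenance (or switching) percentage against divergence time, one
#' colour and regression line per category.
#'
#' @param object A `regevo_rate_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.regevo_rate_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$divergence_mya, y = .data$fraction_pct,
                               colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(
      data = object$fits,
      mapping = ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                             colour = .data$category)
    ) +
    ggplot2::labs(x = "Divergence time (MY)", y = "Maintained regions (%)",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot a signature transition model
#'
#' Heatmap of ancestral-to-derived transition probabilities.
#'
#' @param object A `regevo_transition_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.regevo_transition_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$derived, y = .data$ancestral,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$probability))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Derived signature", y = "Ancestral signature") +
    ggplot2::theme_minimal()
}

#' Heatmap of relative repeat-subgroup enrichment
#'
#' Displays `delta` (percentage-point difference between the two region
#' sets) per repeat subgroup, optionally faceted by species and region
#' class, honouring the `displayed` minimum-count filter.
#'
#' @param enrichment Output of [relative_enrichment()], possibly with
#'   `species`/`region_class` columns as produced by [run_pipeline()].
#' @param displayed_only Show only cells passing the count filter.
#'   Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(enrichment, displayed_only = TRUE) {
  d <- enrichment
  if (displayed_only && "displayed" %in% names(d)) d <- filter(d, .data$displayed)
  has_facets <- all(c("species", "region_class") %in% names(d))
  y <- if (has_facets) "species" else "repeat_class"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$subgroup, y = .data[[y]],
                                       fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "Repeat subgroup", fill = "Delta (pct pts)") +
    ggplot2::theme_minimal()
  if (has_facets) p <- p + ggplot2::facet_wrap(~region_class)
  p
}
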