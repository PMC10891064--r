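# ggplot2 views of the main result types. These return plot objects and
# never print; aesthetics follow the field's conventions (PCoA scatter
# with % variance on the axes, Zi/Pi role plane with threshold lines,
# turnover scatter with its regression line).

#' Plot a PCoA ordination
#'
#' @param x A `pcoa_res`.
#' @param metadata Optional metadata joined by `sample_id`.
#' @param colour Metadata column mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(x, metadata = NULL, colour = "treatment", ...) {
  df <- x$coordinates
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", x$pct_variance[1]),
      y = sprintf("PCo2 (%.1f%%)", x$pct_variance[2])) +
    ggplot2::theme_minimal()
  if (!is.null(metadata) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' @method autoplot pcoa_res
#' @export
autoplot.pcoa_res <- function(object, ...) plot_pcoa(object, ...)

#' Plot a turnover regression
#'
#' Scatter of Bray-Curtis distance against temporal distance (or stage
#' day for divergence fits) with the fitted OLS line.
#'
#' @param object A `turnover_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turnover_fit
#' @export
autoplot.turnover_fit <- function(object, ...) {
  xl <- if (object$mode == "decay") "Temporal distance (days)" else
    "Stage (days post germination)"
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$delta_day, .data$distance)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = xl, y = "Bray-Curtis distance",
      title = sprintf("%s: slope %.4f / d, R2 = %.2f", object$treatment,
                      object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot node roles in the Zi/Pi plane
#'
#' @param roles Result of [node_roles()].
#' @param zi_threshold,pi_threshold Threshold lines (module hubs above
#'   `zi_threshold`, connectors right of `pi_threshold`).
#' @return A ggplot object.
#' @export
plot_node_roles <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(.data$Pi, .data$Zi,
                                      colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = zi_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module degree (Zi)") +
    ggplot2::theme_minimal()
}

#' Plot cumulative module abundance by treatment
#'
#' Boxplots of per-(treatment, stage) mean module loads, one panel per
#' module.
#'
#' @param mod_abund Result of [module_abundance()].
#' @return A ggplot object.
#' @export
plot_module_abundance <- function(mod_abund) {
  means <- module_stage_means(mod_abund)
  ggplot2::ggplot(means, ggplot2::aes(.data$treatment, .data$mean_abundance,
                                      fill = .data$treatment)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~module, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Module load (16S copies / g, stage means)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a co-occurrence network
#'
#' Force-directed layout with nodes coloured by module.
#'
#' @param net A `co_network` (modules optional).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 1) {
  g <- net$graph
  xy <- with_seed_if(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(net$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(
    net$edges,
    dplyr::select(nodes, from_node = "node", x0 = "x", y0 = "y"),
    by = c("from" = "from_node"))
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, to_node = "node", x1 = "x", y1 = "y"),
    by = c("to" = "to_node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$module), size = 2) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
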