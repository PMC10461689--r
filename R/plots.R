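#' Plot a hill-of-vision surface
#'
#' Filled-contour map of a fitted surface over the integration domain, with
#' the test points overlaid.
#'
#' @param interp Fitted [fit_tps()] surface.
#' @param domain Optional [integration_domain()]; defaults to the node hull.
#' @param resolution Raster resolution for display (degrees).
#' @return A ggplot object.
#' @export
plot_hov_surface <- function(interp, domain = NULL, resolution = 0.1) {
  stopifnot(inherits(interp, "hov_tps"))
  if (is.null(domain))
    domain <- integration_domain("convex_hull", points = interp$nodes)
  wt <- domain_weights(domain, resolution)
  df <- data.frame(x = wt$x, y = wt$y,
                   z = predict(interp, cbind(wt$x, wt$y)))
  nodes <- data.frame(x = interp$nodes[, 1], y = interp$nodes[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z), colour = "white",
                          linewidth = 0.2, bins = 10) +
    ggplot2::geom_point(data = nodes, shape = 3, size = 1) +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = sprintf("Hill of vision (%s engine)",
                                  interp$engine)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Mean-difference scatter with the bias (solid) and 95% limits of
#' agreement (dashed) lines.
#'
#' @param agreement A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(agreement) {
  stopifnot(inherits(agreement, "hov_agreement"))
  df <- data.frame(m = agreement$means, d = agreement$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = agreement$bias) +
    ggplot2::geom_hline(yintercept = c(agreement$loa_low,
                                       agreement$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("mean of %s and %s", agreement$metric_a,
                              agreement$metric_b),
                  y = sprintf("%s - %s", agreement$metric_a,
                              agreement$metric_b),
                  title = sprintf("Bland-Altman: bias %.3g [%.3g, %.3g]",
                                  agreement$bias, agreement$loa_low,
                                  agreement$loa_high)) +
    ggplot2::theme_minimal()
}

#' Variable-importance plot
#'
#' Horizontal bar chart of fixed-effect t-statistics (signs preserved),
#' ordered by magnitude.
#'
#' @param fit An [fit_lmm()] result.
#' @return A ggplot object.
#' @export
plot_importance <- function(fit) {
  imp <- variable_importance(fit)
  imp$term <- factor(imp$term, levels = rev(imp$term))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$t, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-1.96, 1.96), linetype = "dotted") +
    ggplot2::labs(x = "t-statistic", y = NULL,
                  title = sprintf("Variable importance for %s",
                                  fit$outcome)) +
    ggplot2::theme_minimal()
}
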