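# ggplot2 graphics for ordination, degree distributions and associations.

#' Plot PCoA sample coordinates
#'
#' @param object An `mh_pcoa`.
#' @param groups Optional per-sample grouping to colour by (aligned with the
#'   coordinate rows).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mh_pcoa <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", object$variance_explained[1]),
      y = sprintf("Axis 2 (%.1f%%)",
                  if (length(object$variance_explained) > 1)
                    object$variance_explained[2] else 0)
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
}

#' Plot a network degree histogram with fitted degree models
#'
#' Overlays the maximum-likelihood power-law and zero-truncated Poisson
#' probability mass functions (scaled to counts) on the observed degree
#' histogram; a scale-free network tracks the power law, a random graph the
#' Poisson curve.
#'
#' @param object An `mh_topology`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mh_topology <- function(object, ...) {
  h <- object$degree_histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$degree, .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "degree k", y = "number of nodes") +
    ggplot2::theme_minimal()
  fit <- object$fit
  if (!is.null(fit) && is.finite(fit$alpha)) {
    ks <- seq(max(1, min(h$degree)), max(h$degree))
    n <- fit$n
    pow <- ks^(-fit$alpha) / hurwitz_zeta(fit$alpha, 1)
    pois <- stats::dpois(ks, fit$lambda) / (1 - stats::dpois(0, fit$lambda))
    curves <- tibble::tibble(
      degree = rep(ks, 2),
      count = c(n * pow, n * pois),
      model = rep(c("power law", "Poisson"), each = length(ks))
    )
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$degree, .data$count, colour = .data$model),
      linewidth = 0.8
    ) +
      ggplot2::labs(subtitle = paste("classified:", fit$model))
  }
  p
}

#' Heatmap of taxon-phenotype Spearman correlations
#'
#' @param assoc Long association tibble from [associate()].
#' @param label_significant Mark cells with raw p below 0.05?
#' @return A ggplot.
#' @export
plot_association_heatmap <- function(assoc, label_significant = TRUE) {
  p <- ggplot2::ggplot(assoc,
                       ggplot2::aes(.data$variable, .data$taxon, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
  if (label_significant) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(assoc, .data$significant),
      label = "*", size = 5
    )
  }
  p
}
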