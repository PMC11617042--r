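# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-occurrence network into its edge table
#'
#' @param x An `mh_network`.
#' @param ... Unused.
#' @return Tibble with one row per edge: `source`, `target`, `rho`, `p`,
#'   `sign`.
#' @export
tidy.mh_network <- function(x, ...) x$edges

#' One-row network summary
#'
#' @param x An `mh_network`.
#' @param ... Unused.
#' @return Tibble with node, edge and sign counts.
#' @export
glance.mh_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_positive = sum(x$edges$sign > 0),
                 n_negative = sum(x$edges$sign < 0))
}

#' One-row topology summary
#'
#' @param x An `mh_topology`.
#' @param ... Unused.
#' @return Tibble with counts, average degree, clustering coefficients and
#'   (when fitted) the degree-model parameters and classification.
#' @export
glance.mh_topology <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    average_degree = x$average_degree,
    transitivity = x$transitivity,
    mean_local_clustering = x$mean_local_clustering,
    alpha = if (is.null(x$fit)) NA_real_ else x$fit$alpha,
    lambda = if (is.null(x$fit)) NA_real_ else x$fit$lambda,
    degree_model = if (is.null(x$fit)) NA_character_ else x$fit$model
  )
}

#' Tidy the degree histogram of a topology result
#'
#' @param x An `mh_topology`.
#' @param ... Unused.
#' @return Tibble with `degree` and `count`.
#' @export
tidy.mh_topology <- function(x, ...) x$degree_histogram

#' Tidy a hub set
#'
#' @param x An `mh_hubs`.
#' @param ... Unused.
#' @return Tibble with `taxon` and `degree` of each hub.
#' @export
tidy.mh_hubs <- function(x, ...) x$hubs

#' Tidy PCoA coordinates
#'
#' @param x An `mh_pcoa`.
#' @param ... Unused.
#' @return Tibble of sample coordinates.
#' @export
tidy.mh_pcoa <- function(x, ...) x$coordinates

#' One-row PCoA summary
#'
#' @param x An `mh_pcoa`.
#' @param ... Unused.
#' @return Tibble with axis count and the first two axes' percent variance.
#' @export
glance.mh_pcoa <- function(x, ...) {
  tibble::tibble(n_axes = length(x$variance_explained),
                 pve_axis1 = x$variance_explained[1],
                 pve_axis2 = if (length(x$variance_explained) > 1)
                   x$variance_explained[2] else NA_real_)
}

#' One-row PERMANOVA summary
#'
#' @param x An `mh_permanova`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `p_value`, `n_perm`.
#' @export
glance.mh_permanova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm)
}
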