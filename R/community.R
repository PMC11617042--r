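# Alpha diversity, Bray-Curtis dissimilarity, classical PCoA and one-way
# PERMANOVA for two-condition community comparisons.

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i ln p_i)` over features with positive abundance, in nats.
#' Zero-count features do not contribute; a single-species sample has H = 0.
#'
#' @param x Non-negative abundance vector with at least one positive entry.
#' @return Shannon index (nats).
#' @export
shannon <- function(x) {
  check_sample_vector(x)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Gini-Simpson diversity of one sample
#'
#' `1 - sum(p_i^2)`; 0 for a single species, approaches `1 - 1/S` for a
#' uniform community of S species.
#'
#' @inheritParams shannon
#' @return Simpson index in `[0, 1)`.
#' @export
simpson <- function(x) {
  check_sample_vector(x)
  unname(vegan::diversity(x, index = "simpson"))
}

check_sample_vector <- function(x) {
  if (!is.numeric(x) || any(x < 0)) stop("abundances must be non-negative numbers", call. = FALSE)
  if (all(x == 0)) stop("all-zero sample: diversity is undefined", call. = FALSE)
  invisible(x)
}

#' Per-sample alpha diversity of an abundance table
#'
#' @param table An abundance table tibble.
#' @return Tibble with `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table) {
  m <- abund_matrix(table)
  tibble::tibble(
    sample_id = colnames(m),
    shannon = unname(apply(m, 2, shannon)),
    simpson = unname(apply(m, 2, simpson))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`, bounded in `[0, 1]`:
#' 0 for identical samples, 1 for disjoint supports.
#'
#' @param table An abundance table tibble, or a features x samples matrix.
#' @return Symmetric samples x samples distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- if (is.matrix(table)) table else abund_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(colSums(m) == 0)) {
    stop("all-zero sample(s): Bray-Curtis denominator undefined", call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition. Axes
#' with eigenvalues above a small positive tolerance are retained; negative
#' eigenvalues are dropped without correction; percent variance explained is
#' computed over the positive eigenvalues only.
#'
#' @param distances Symmetric distance matrix with zero diagonal.
#' @param tol Relative eigenvalue tolerance for axis retention.
#' @return Object of class `mh_pcoa`: list with `coordinates` (tibble:
#'   sample_id + Axis columns), `variance_explained` (percent per axis), and
#'   `eigenvalues`.
#' @export
pcoa <- function(distances, tol = 1e-8) {
  distances <- as.matrix(distances)
  if (max(abs(distances - t(distances))) > 1e-10) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(distances)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(distances), k = n - 1, eig = TRUE))
  ev <- fit$eig
  k <- min(ncol(fit$points), sum(ev > tol * max(abs(ev))))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  ids <- rownames(distances) %||% paste0("s", seq_len(n))
  coords <- tibble::as_tibble(pts, .name_repair = ~ paste0("Axis", seq_len(k)))
  coords <- dplyr::bind_cols(tibble::tibble(sample_id = ids), coords)
  pve <- 100 * ev[seq_len(k)] / sum(ev[ev > 0])
  structure(list(coordinates = coords,
                 variance_explained = pve,
                 eigenvalues = ev),
            class = "mh_pcoa")
}

#' @export
print.mh_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,",
      length(x$variance_explained), "axes retained;",
      "Axis1 =", signif(x$variance_explained[1], 3), "%\n")
  invisible(x)
}

# Pseudo-F from a squared-distance matrix and integer group codes.
permanova_f <- function(d2, groups) {
  n <- length(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  g <- length(unique(groups))
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

#' One-way PERMANOVA
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and tests the pseudo-F statistic by random
#' permutation of the group labels. The p-value uses the add-one estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` and so is never zero.
#'
#' @param distances Symmetric distance matrix.
#' @param groups Group labels (2 groups, each with >= 2 samples), in the
#'   same order as the rows of `distances`.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return Object of class `mh_permanova`: list with `statistic` (pseudo-F),
#'   `p_value`, `n_perm`, and group sizes.
#' @export
permanova <- function(distances, groups, n_perm = 999, seed = NULL) {
  distances <- as.matrix(distances)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("permanova here supports exactly 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples", call. = FALSE)
  if (length(groups) != nrow(distances)) stop("groups and distances disagree in length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d2 <- distances^2
  g <- as.integer(groups)
  f_obs <- permanova_f(d2, g)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (permanova_f(d2, sample(g)) >= f_obs) hits <- hits + 1L
  }
  structure(list(statistic = f_obs,
                 p_value = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm,
                 n_per_group = as.integer(table(groups))),
            class = "mh_permanova")
}

#' @export
print.mh_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}
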