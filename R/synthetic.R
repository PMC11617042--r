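# Synthetic two-condition compositional studies with planted network
# topology, differential taxa, and taxa-coupled phenotypes.
#
# The observation model matches the assumptions of the correlation
# inference: latent absolute log-abundances are multivariate normal with a
# correlation matrix carrying the planted network (a Gaussian copula on the
# log scale), abundances are exponentiated and normalized to fractions, and
# counts are multinomial at a fixed sequencing depth.

make_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

#' Generate a planted interaction network with signed edges
#'
#' Scale-free graphs come from preferential attachment (`m` edges per
#' arriving node, the Barabási–Albert model); random graphs are
#' Erdős–Rényi `G(D, p)`. Each edge receives a sign, negative with
#' probability `prob_negative`.
#'
#' @param topology `"scale_free"` or `"random"`.
#' @param D Number of taxa (nodes).
#' @param param `m` (edges per new node) for scale-free; `p` (edge
#'   probability) for random.
#' @param prob_negative Probability an edge is antagonistic (negative).
#' @param seed Optional integer seed.
#' @return Undirected igraph with an edge attribute `sign` in \{-1, +1\}.
#' @export
generate_planted_network <- function(topology = c("scale_free", "random"),
                                     D, param, prob_negative = 0.5,
                                     seed = NULL) {
  topology <- match.arg(topology)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(topology,
    scale_free = {
      if (param >= D) stop("m must be smaller than D", call. = FALSE)
      igraph::sample_pa(D, m = param, directed = FALSE)
    },
    random = {
      if (param <= 0 || param >= 1) stop("p must lie in (0, 1)", call. = FALSE)
      igraph::sample_gnp(D, param)
    }
  )
  igraph::V(g)$name <- paste0("taxon_", formatC(seq_len(D), width = nchar(D), flag = "0"))
  igraph::E(g)$sign <- sample(c(-1L, 1L), igraph::ecount(g), replace = TRUE,
                              prob = c(prob_negative, 1 - prob_negative))
  g
}

# Weighted nearest-correlation projection (alternating projections with
# Dykstra correction in the W-norm, diagonal node weights).
nearcor_weighted <- function(target, weights, floor = 1e-6, maxit = 300,
                             tol = 1e-8) {
  ws <- sqrt(weights)
  Wh <- outer(ws, ws)
  Y <- target
  dS <- matrix(0, nrow(target), ncol(target))
  for (it in seq_len(maxit)) {
    R <- Y - dS
    e <- eigen(R * Wh, symmetric = TRUE)
    X <- (e$vectors %*% (pmax(e$values, 0) * t(e$vectors))) / Wh
    X <- (X + t(X)) / 2
    dS <- X - R
    Y_old <- Y
    Y <- X
    diag(Y) <- 1
    if (max(abs(Y - Y_old)) < tol) break
  }
  e <- eigen(Y, symmetric = TRUE)
  if (min(e$values) < floor) {
    X <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    d <- sqrt(diag(X))
    Y <- X / outer(d, d)
  }
  Y
}

#' Embed a planted signed network in a positive-definite correlation matrix
#'
#' Starts from the identity with `+-c` at planted edges and repairs to a
#' positive-definite correlation matrix by weighted nearest-correlation
#' projection (node weights 1 + degree, protecting hub rows), then boosts
#' the planted entries back toward `+-c` in small steps while the largest
#' background (non-edge) correlation stays below `fill_cap`. A hub of
#' degree k cannot hold all its edges at magnitude c unless its neighbours
#' correlate at about `c^2` among themselves, so some deviation from the
#' target is unavoidable for `k > 1/c^2`; the achieved maximum deviation at
#' planted entries and the largest background fill are reported as
#' attributes, with a warning when the planted deviation exceeds `c / 2`.
#'
#' @param graph Planted igraph with edge attribute `sign`.
#' @param c Edge correlation magnitude in (0, 1).
#' @param fill_cap Largest tolerated background correlation magnitude.
#' @param eta Boost step size.
#' @param max_boost_rounds Maximum boost iterations.
#' @param floor Eigenvalue floor for positive definiteness.
#' @return Correlation matrix (taxa dimnames from the graph) with attributes
#'   `max_planted_deviation` and `max_fill`.
#' @export
network_to_correlation <- function(graph, c, fill_cap = 0.32, eta = 0.25,
                                   max_boost_rounds = 25, floor = 1e-6) {
  if (c <= 0 || c >= 1) stop("c must lie in (0, 1)", call. = FALSE)
  D <- igraph::vcount(graph)
  taxa <- igraph::V(graph)$name
  target <- diag(D)
  dimnames(target) <- list(taxa, taxa)
  if (igraph::ecount(graph) == 0) {
    attr(target, "max_planted_deviation") <- 0
    attr(target, "max_fill") <- 0
    return(target)
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  s <- igraph::E(graph)$sign
  target[el] <- c * s
  target[el[, 2:1, drop = FALSE]] <- c * s
  mask <- target != 0 & !diag(D)  # planted entries
  free <- !mask & !diag(D)
  w <- 1 + igraph::degree(graph)
  tgt <- target
  C <- nearcor_weighted(tgt, w, floor = floor)
  best <- C
  for (r in seq_len(max_boost_rounds)) {
    tgt[mask] <- tgt[mask] + eta * (target[mask] - C[mask])
    C <- nearcor_weighted(tgt, w, floor = floor)
    if (any(free) && max(abs(C[free])) > fill_cap) break
    best <- C
  }
  dev <- max(abs(best[mask] - target[mask]))
  if (dev > c / 2) {
    warning(sprintf(
      "planted-entry deviation %.3f exceeds c/2 = %.3f; consider a smaller c or a sparser graph",
      dev, c / 2), call. = FALSE)
  }
  dimnames(best) <- list(taxa, taxa)
  attr(best, "max_planted_deviation") <- dev
  attr(best, "max_fill") <- if (any(free)) max(abs(best[free])) else 0
  best
}

#' Draw compositional counts from a latent log-normal basis
#'
#' Per sample: latent log-abundances are multivariate normal with the given
#' correlation matrix and per-taxon means/standard deviations (means of
#' differential taxa shifted by `ln(2) * log2_fc`), exponentiated,
#' normalized to fractions, and observed as multinomial counts at the given
#' depth.
#'
#' @param correlation Positive-definite correlation matrix (D x D).
#' @param log_mean,log_sd Per-taxon latent means and standard deviations.
#' @param n_samples Number of samples.
#' @param depth Sequencing depth (reads per sample).
#' @param log2_fc Per-taxon log2 fold change added to the latent means
#'   (scalar or length-D vector).
#' @param seed Optional integer seed.
#' @return List with `counts` (taxa x samples integer matrix, columns
#'   summing to `depth`) and `latent` (samples x taxa log-abundances).
#' @export
generate_counts <- function(correlation, log_mean, log_sd, n_samples, depth,
                            log2_fc = 0, seed = NULL) {
  D <- nrow(correlation)
  if (depth < 10 * D) {
    warning("depth below 10 reads per taxon: sparse counts degrade inference",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- rep(log_mean, length.out = D) + log(2) * rep(log2_fc, length.out = D)
  sd <- rep(log_sd, length.out = D)
  L <- chol(correlation)
  Z <- matrix(stats::rnorm(n_samples * D), n_samples, D) %*% L
  latent <- sweep(sweep(Z, 2, sd, "*"), 2, mu, "+")
  frac <- exp(latent)
  frac <- frac / rowSums(frac)
  counts <- vapply(seq_len(n_samples),
                   function(i) stats::rmultinom(1, depth, frac[i, ])[, 1],
                   numeric(D))
  rownames(counts) <- rownames(correlation)
  colnames(latent) <- rownames(correlation)
  list(counts = counts, latent = latent)
}

#' Configuration for a synthetic two-condition study
#'
#' Defaults mirror a diet-intervention mucosal-microbiome design scaled up
#' for statistical power: 60 taxa, 20 samples per group at depth 100,000,
#' a scale-free (preferential attachment, m = 2) interaction network in the
#' control group against an Erdős–Rényi random graph with matched expected
#' edge count in the case group, planted edge correlation 0.6 with random
#' signs, 10 differential taxa at |log2 FC| = 2, and two permeability-like
#' phenotypes negatively coupled to the five highest-degree control-network
#' hubs. A `small_cohort = TRUE` preset (n = 5 per group) mirrors a typical
#' mouse-experiment cohort size for demonstration.
#'
#' @param D Number of taxa (>= 10).
#' @param n_per_group Samples per group (>= 5).
#' @param groups Two group labels (control first).
#' @param topology Named list (one entry per group) with elements
#'   `type` ("scale_free"/"random") and `param`.
#' @param edge_cor Planted edge correlation magnitude in (0, 1).
#' @param prob_negative Probability an edge is negative.
#' @param log_mean_range,log_sd_range Ranges for per-taxon latent means/SDs.
#' @param depth Reads per sample.
#' @param n_differential Number of differential taxa (half up, half down).
#' @param log2_fc Absolute log2 fold change of differential taxa.
#' @param phenotypes Named list of phenotype specs, each a list with
#'   `n_taxa` (coupled to the top planted hubs) or `taxa` (explicit ids),
#'   `coef` (per-taxon coefficient, recycled), and `noise_sd` (NULL matches
#'   the noise to the signal SD).
#' @param covariate List with `name`, `mean`, `sd` for the independent
#'   numeric covariate.
#' @param small_cohort Use a mouse-experiment-sized cohort (n = 5 per group).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `mh_config`.
#' @export
synthetic_config <- function(D = 60, n_per_group = 20,
                             groups = c("Ctrl", "HFD"),
                             topology = NULL,
                             edge_cor = 0.6, prob_negative = 0.5,
                             log_mean_range = c(0, 3),
                             log_sd_range = c(0.5, 1.5),
                             depth = 1e5,
                             n_differential = 10, log2_fc = 2,
                             phenotypes = NULL,
                             covariate = list(name = "body_weight", mean = 25, sd = 2),
                             small_cohort = FALSE,
                             seed = 1) {
  if (D < 10) stop("D must be at least 10", call. = FALSE)
  if (small_cohort) n_per_group <- 5
  if (n_per_group < 5) stop("n_per_group must be at least 5", call. = FALSE)
  if (is.null(topology)) {
    m <- 2
    topology <- stats::setNames(list(
      list(type = "scale_free", param = m),
      list(type = "random", param = 2 * m / (D - 1))  # matched expected edges
    ), groups)
  }
  if (is.null(phenotypes)) {
    phenotypes <- list(
      fitc_dextran = list(n_taxa = 5, coef = -1, noise_sd = NULL),
      alt = list(n_taxa = 5, coef = -1, noise_sd = NULL)
    )
  }
  structure(list(D = D, n_per_group = n_per_group, groups = groups,
                 topology = topology, edge_cor = edge_cor,
                 prob_negative = prob_negative,
                 log_mean_range = log_mean_range, log_sd_range = log_sd_range,
                 depth = depth, n_differential = n_differential,
                 log2_fc = log2_fc, phenotypes = phenotypes,
                 covariate = covariate, seed = seed),
            class = "mh_config")
}

#' Generate a complete synthetic study with ground truth
#'
#' Builds each group's planted network, embeds it in a correlation matrix,
#' draws compositional counts, attaches metadata (group, covariate,
#' phenotypes coupled to designated taxa via the latent log-abundances), and
#' records the full ground truth: planted networks, strict-Q3 hub sets of
#' the planted degree distributions, differential taxa, and phenotype
#' coefficients. Deterministic given the config seed.
#'
#' @param config An [synthetic_config()] object.
#' @return Object of class `mh_study`: list with `table` (abundance tibble),
#'   `metadata` (tibble), and `truth`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "mh_config"))
  D <- config$D
  groups <- config$groups
  seed <- config$seed

  set.seed(make_seed(seed, 1))
  log_mean <- stats::runif(D, config$log_mean_range[1], config$log_mean_range[2])
  log_sd <- stats::runif(D, config$log_sd_range[1], config$log_sd_range[2])

  # differential taxa: half enriched in the case group, half depleted
  idx_diff <- sort(sample.int(D, config$n_differential))
  lfc <- numeric(D)
  half <- length(idx_diff) %/% 2
  lfc[idx_diff[seq_len(half)]] <- config$log2_fc
  lfc[idx_diff[-seq_len(half)]] <- -config$log2_fc

  nets <- list()
  cors <- list()
  counts_list <- list()
  latents <- list()
  for (gi in seq_along(groups)) {
    gname <- groups[gi]
    top <- config$topology[[gname]]
    g <- generate_planted_network(top$type, D, top$param,
                                  prob_negative = config$prob_negative,
                                  seed = make_seed(seed, 10 + gi))
    C <- network_to_correlation(g, config$edge_cor)
    fc <- if (gi == 1) 0 else lfc  # fold changes shift the case group
    gc <- generate_counts(C, log_mean, log_sd, config$n_per_group,
                          config$depth, log2_fc = fc,
                          seed = make_seed(seed, 20 + gi))
    colnames(gc$counts) <- paste0(gname, "_",
                                  formatC(seq_len(config$n_per_group), width = 2, flag = "0"))
    nets[[gname]] <- g
    cors[[gname]] <- C
    counts_list[[gname]] <- gc$counts
    latents[[gname]] <- gc$latent
  }
  counts <- do.call(cbind, counts_list)
  latent <- do.call(rbind, latents)
  taxa <- rownames(counts)

  # phenotypes coupled to designated taxa through the latent log-abundances
  planted_deg <- igraph::degree(nets[[groups[1]]])
  hub_order <- order(planted_deg, decreasing = TRUE)
  set.seed(make_seed(seed, 40))
  phen <- list()
  phen_truth <- list()
  for (pn in names(config$phenotypes)) {
    spec <- config$phenotypes[[pn]]
    ptaxa <- if (!is.null(spec$taxa)) spec$taxa else taxa[hub_order[seq_len(spec$n_taxa)]]
    missing <- setdiff(ptaxa, taxa)
    if (length(missing)) {
      stop("phenotype '", pn, "' designates unknown taxa: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    coef <- rep(spec$coef, length.out = length(ptaxa))
    signal <- as.vector(latent[, ptaxa, drop = FALSE] %*% coef)
    noise_sd <- spec$noise_sd %||% stats::sd(signal)
    if (noise_sd == 0) noise_sd <- 1  # e.g. all-zero coefficients
    phen[[pn]] <- signal + stats::rnorm(length(signal), 0, noise_sd)
    phen_truth[[pn]] <- list(taxa = ptaxa, coef = coef, noise_sd = noise_sd)
  }
  covariate <- stats::rnorm(ncol(counts), config$covariate$mean, config$covariate$sd)

  metadata <- tibble::tibble(
    sample_id = colnames(counts),
    group = factor(rep(groups, each = config$n_per_group), levels = groups)
  )
  metadata[[config$covariate$name]] <- covariate
  for (pn in names(phen)) metadata[[pn]] <- phen[[pn]]

  truth <- list(
    networks = nets,
    correlations = cors,
    hubs = lapply(nets, function(g) hubs_from_degrees(igraph::degree(g))),
    differential = tibble::tibble(
      feature_id = taxa[idx_diff],
      log2_fc = lfc[idx_diff],
      direction = ifelse(lfc[idx_diff] > 0, groups[2], groups[1])
    ),
    phenotypes = phen_truth,
    latent = latent,
    config = config
  )
  structure(list(table = abundance_table(counts, kind = "taxa"),
                 metadata = metadata, truth = truth),
            class = "mh_study")
}

#' @export
print.mh_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$table), "taxa x", nrow(x$metadata), "samples;",
      nrow(x$truth$differential), "differential taxa\n")
  invisible(x)
}
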