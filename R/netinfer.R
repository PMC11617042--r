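# Compositional correlation inference and co-occurrence network analysis.
#
# Sequencing counts are compositional: per-sample totals are arbitrary, so
# Pearson correlations on fractions are spurious. The estimator here works
# from log-ratio variances t_ij = Var ln(x_i/x_j), which are invariant to
# per-sample scaling. Under the sparsity approximation (most taxa weakly
# correlated) the basis variances omega_i^2 of latent absolute log
# abundances solve a linear system in the row sums of T, and basis
# correlations follow as
#   rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j).
# Strongly correlated pairs violate the approximation, so the strongest
# pair is iteratively excluded from the system and the basis re-solved.
# Count uncertainty is propagated by resampling sample fractions from a
# Dirichlet posterior and taking the element-wise median across draws.

#' Draw per-sample fraction matrices from a Dirichlet posterior
#'
#' Each draw resamples every sample's composition from
#' Dirichlet(counts + 1); the unit prior pseudocount keeps zero counts
#' strictly positive so log-ratios exist.
#'
#' @param table An abundance table tibble (taxa kind), or a counts matrix
#'   (features x samples).
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed (draws are reproducible given it).
#' @param prior Dirichlet prior pseudocount added to every taxon.
#' @return List of `n_draws` matrices, samples x taxa, rows summing to 1.
#' @export
estimate_fractions <- function(table, n_draws = 20, seed = NULL, prior = 1) {
  counts <- if (is.matrix(table)) table else abund_matrix(table)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(counts) < 4L) {
    stop("need at least 4 taxa: the basis variance system is degenerate below D = 4",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- t(counts) + prior  # samples x taxa
  lapply(seq_len(n_draws), function(d) {
    g <- matrix(stats::rgamma(length(a), shape = a), nrow = nrow(a),
                dimnames = dimnames(a))
    g / rowSums(g)
  })
}

#' Log-ratio variance matrix
#'
#' Computes `t_ij`, the sample variance (denominator n - 1) of
#' `ln(x_i / x_j)` across samples, for every taxon pair. The matrix is
#' symmetric with zero diagonal and is invariant to per-sample rescaling of
#' the fractions.
#'
#' @param fractions Strictly positive matrix, samples x taxa.
#' @return Symmetric taxa x taxa matrix of log-ratio variances.
#' @export
logratio_variances <- function(fractions) {
  if (any(fractions <= 0)) stop("fractions must be strictly positive", call. = FALSE)
  if (nrow(fractions) < 3L) stop("need at least 3 samples for log-ratio variances", call. = FALSE)
  L <- log(fractions)
  V <- stats::cov(L)
  v <- diag(V)
  Tm <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * V
  Tm[Tm < 0] <- 0  # numerical guard; exact zeros for proportional taxa
  diag(Tm) <- 0
  dimnames(Tm) <- list(colnames(fractions), colnames(fractions))
  Tm
}

#' Solve the basis variance system and derive basis correlations
#'
#' Under the sparsity approximation, row sums of the log-ratio variance
#' matrix satisfy `t_i = d_i * omega_i^2 + sum_{j in allowed(i)} omega_j^2`
#' where `d_i` counts the allowed partners of taxon i. With no exclusions
#' this is the symmetric system `((D - 2) I + J) omega^2 = t`. Non-positive
#' solutions are clipped to a small positive floor and the implied
#' correlations clipped to `[-1, 1]`; pairs whose variance hit the floor get
#' correlation 0.
#'
#' @param T_mat Symmetric log-ratio variance matrix (zero diagonal).
#' @param excluded_pairs Optional 2-column integer matrix of taxon index
#'   pairs excluded from the system.
#' @param var_floor Positive floor applied to the solved basis variances.
#' @return List with `omega_sq` (basis variances), `rho` (basis correlation
#'   matrix, unit diagonal) and `excluded_pairs`.
#' @export
solve_basis <- function(T_mat, excluded_pairs = NULL, var_floor = 1e-8) {
  D <- nrow(T_mat)
  if (D < 4L) stop("need at least 4 taxa", call. = FALSE)
  allowed <- matrix(TRUE, D, D)
  diag(allowed) <- FALSE
  if (!is.null(excluded_pairs) && nrow(excluded_pairs)) {
    allowed[excluded_pairs] <- FALSE
    allowed[excluded_pairs[, 2:1, drop = FALSE]] <- FALSE
  }
  A <- allowed * 1
  diag(A) <- rowSums(allowed)
  ti <- rowSums(T_mat * allowed)
  qrA <- qr(A)
  if (qrA$rank < D) {
    stop("basis system is rank-deficient after exclusions; use fewer exclusions",
         call. = FALSE)
  }
  omega_sq <- qr.coef(qrA, ti)
  floored <- omega_sq < var_floor
  omega_sq <- pmax(omega_sq, var_floor)
  om <- sqrt(omega_sq)
  rho <- (outer(omega_sq, rep(1, D)) + outer(rep(1, D), omega_sq) - T_mat) /
    (2 * outer(om, om))
  rho <- pmin(pmax(rho, -1), 1)
  if (any(floored)) {
    rho[floored, ] <- 0
    rho[, floored] <- 0
  }
  diag(rho) <- 1
  dimnames(rho) <- dimnames(T_mat)
  names(omega_sq) <- rownames(T_mat)
  list(omega_sq = omega_sq, rho = rho,
       excluded_pairs = if (is.null(excluded_pairs)) matrix(0L, 0, 2) else excluded_pairs)
}

# One basis-correlation estimate from a single fraction matrix, with the
# iterative strong-pair exclusion loop.
sparcc_single <- function(fractions, exclusion_threshold = 0.1,
                          max_exclusion_rounds = 10) {
  Tm <- logratio_variances(fractions)
  excl <- matrix(0L, 0, 2)
  fit <- solve_basis(Tm, excl)
  for (round in seq_len(max_exclusion_rounds)) {
    R <- abs(fit$rho)
    diag(R) <- 0
    if (nrow(excl)) {
      R[excl] <- 0
      R[excl[, 2:1, drop = FALSE]] <- 0
    }
    top <- which.max(R)
    if (R[top] < exclusion_threshold) break
    excl <- rbind(excl, arrayInd(top, dim(R)))
    refit <- tryCatch(solve_basis(Tm, excl), error = function(e) NULL)
    if (is.null(refit)) break  # keep last solvable fit
    fit <- refit
  }
  fit$rho
}

#' Basis correlations for an abundance table (SparCC-style)
#'
#' For each Dirichlet fraction draw the basis system is solved with
#' iterative exclusion of the most strongly correlated pair (per-draw, up to
#' `max_exclusion_rounds` rounds, pairs with `|rho|` below
#' `exclusion_threshold` never excluded); the returned matrix is the
#' element-wise median across draws. Deterministic given `seed`.
#'
#' @inheritParams estimate_fractions
#' @param exclusion_threshold Minimum `|rho|` for a pair to be excluded.
#' @param max_exclusion_rounds Maximum exclusion iterations per draw.
#' @return Symmetric basis correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_draws = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, seed = NULL) {
  fracs <- estimate_fractions(table, n_draws = n_draws, seed = seed)
  draws <- vapply(fracs,
                  sparcc_single,
                  FUN.VALUE = matrix(0, ncol(fracs[[1]]), ncol(fracs[[1]])),
                  exclusion_threshold = exclusion_threshold,
                  max_exclusion_rounds = max_exclusion_rounds)
  rho <- apply(draws, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(fracs[[1]]), colnames(fracs[[1]]))
  rho
}

#' Permutation pseudo p-values for basis correlations
#'
#' Each permutation shuffles every taxon's counts independently across
#' samples (destroying inter-taxon association while preserving marginals),
#' re-estimates the correlation matrix, and compares magnitudes. The
#' two-sided add-one estimator
#' `p_ij = (1 + #\{|rho*_ij| >= |rho_ij|\}) / (1 + n_perm)` never returns 0.
#'
#' @inheritParams sparcc
#' @param observed_rho Correlation matrix from [sparcc()] on the same table.
#' @param n_perm Number of permutations.
#' @param n_draws Dirichlet draws per permutation (1 is customary for speed).
#' @return Symmetric matrix of p-values in (0, 1].
#' @export
sparcc_pvalues <- function(table, observed_rho, n_perm = 100, seed = NULL,
                           n_draws = 1, exclusion_threshold = 0.1,
                           max_exclusion_rounds = 10) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  counts <- if (is.matrix(table)) table else abund_matrix(table)
  if (!is.null(seed)) set.seed(seed)
  a_obs <- abs(observed_rho)
  ge <- matrix(0, nrow(a_obs), ncol(a_obs))
  for (b in seq_len(n_perm)) {
    perm <- counts
    for (i in seq_len(nrow(perm))) perm[i, ] <- perm[i, sample.int(ncol(perm))]
    rho_p <- sparcc(perm, n_draws = n_draws,
                    exclusion_threshold = exclusion_threshold,
                    max_exclusion_rounds = max_exclusion_rounds, seed = NULL)
    ge <- ge + (abs(rho_p) >= a_obs)
  }
  p <- (1 + ge) / (1 + n_perm)
  p <- pmax(p, t(p))  # enforce symmetry conservatively
  diag(p) <- 1
  dimnames(p) <- dimnames(observed_rho)
  p
}

new_network <- function(graph, edges) {
  deg <- igraph::degree(graph)
  structure(list(graph = graph, edges = edges,
                 nodes = igraph::V(graph)$name,
                 degree = deg),
            class = "mh_network")
}

#' Build a signed co-occurrence network from correlations and p-values
#'
#' An edge joins taxa i and j iff `|rho_ij| > r_threshold` and
#' `p_ij < p_threshold` (both strict, matching the published filter r > 0.4
#' or r < -0.4 with p < 0.05). Edge sign is the sign of rho. By default the
#' node set contains only taxa incident to at least one kept edge.
#'
#' @param rho Symmetric correlation matrix with taxon dimnames.
#' @param pvals Symmetric p-value matrix conformant with `rho`.
#' @param r_threshold Correlation magnitude threshold in (0, 1).
#' @param p_threshold Significance threshold in (0, 1).
#' @param keep_isolated Keep taxa with no incident edge as isolated nodes?
#' @return An object of class `mh_network`: list with `graph` (igraph),
#'   `edges` (tibble: source, target, rho, p, sign), `nodes`, and `degree`.
#' @export
build_network <- function(rho, pvals, r_threshold = 0.4, p_threshold = 0.05,
                          keep_isolated = FALSE) {
  stopifnot(is.matrix(rho), is.matrix(pvals), all(dim(rho) == dim(pvals)))
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0, 1)", call. = FALSE)
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)", call. = FALSE)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric", call. = FALSE)
  taxa <- rownames(rho)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(rho)))
  keep <- abs(rho) > r_threshold & pvals < p_threshold & upper.tri(rho)
  idx <- which(keep, arr.ind = TRUE)
  rho_kept <- rho[idx]
  edges <- tibble::tibble(
    source = taxa[idx[, 1]],
    target = taxa[idx[, 2]],
    rho = rho_kept,
    p = pvals[idx],
    sign = as.integer(sign(rho_kept))
  )
  nodes <- if (keep_isolated) taxa else sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  new_network(g, edges)
}

#' @export
print.mh_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Topology metrics of a co-occurrence network
#'
#' Reports node and edge counts, average degree (2E/N), global clustering
#' coefficient (transitivity: 3 x triangles / connected triples), mean local
#' clustering (nodes of degree < 2 contribute 0), the degree histogram, and
#' — when at least 10 nodes have degree >= `k_min` — maximum-likelihood
#' power-law and zero-truncated Poisson fits of the degree distribution with
#' the AIC-preferred model.
#'
#' @param network An `mh_network`.
#' @param k_min Minimum degree entering the degree-model fits; `NULL`
#'   (default) anchors at the minimum positive observed degree.
#' @return An object of class `mh_topology` (a list; see [glance.mh_topology]).
#' @export
topology_metrics <- function(network, k_min = NULL) {
  g <- network$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                          transitivity = 0, mean_local_clustering = 0,
                          degree_histogram = tibble::tibble(degree = integer(), count = integer()),
                          fit = NULL),
                     class = "mh_topology"))
  }
  deg <- igraph::degree(g)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  loc <- igraph::transitivity(g, type = "local")
  loc[is.nan(loc) | is.na(loc)] <- 0  # degree < 2 contributes 0
  hist_tbl <- tibble::tibble(degree = as.integer(names(table(deg))),
                             count = as.integer(table(deg)))
  fit <- NULL
  k_fit <- k_min %||% if (any(deg > 0)) min(deg[deg > 0]) else 1
  if (sum(deg >= k_fit) >= 10) {
    fit <- tryCatch(classify_degree_model(deg, k_min = k_fit),
                    error = function(e) NULL)
  }
  structure(list(n_nodes = n, n_edges = e, average_degree = 2 * e / n,
                 transitivity = trans, mean_local_clustering = mean(loc),
                 degree_histogram = hist_tbl, fit = fit),
            class = "mh_topology")
}

#' @export
print.mh_topology <- function(x, ...) {
  cat("Network topology: N =", x$n_nodes, " E =", x$n_edges,
      " <k> =", signif(x$average_degree, 4),
      " transitivity =", signif(x$transitivity, 4), "\n")
  if (!is.null(x$fit)) {
    cat("Degree model:", x$fit$model,
        sprintf("(alpha = %.3f, lambda = %.3f)\n", x$fit$alpha, x$fit$lambda))
  }
  invisible(x)
}

# Hurwitz zeta for alpha > 1 and integer k_min >= 1.
hurwitz_zeta <- function(alpha, k_min) {
  z <- pracma::zeta(alpha)
  if (k_min > 1) z <- z - sum(seq_len(k_min - 1)^(-alpha))
  z
}

#' Classify a degree distribution as power-law or Poisson
#'
#' Fits, on degrees `>= k_min`, (i) a discrete power law by the
#' maximum-likelihood estimate
#' `alpha = 1 + n / sum(ln(k_i / (k_min - 0.5)))` with zeta-normalized
#' log-likelihood, and (ii) a zero-truncated Poisson by Newton iteration on
#' the mean equation `lambda / (1 - exp(-lambda)) = mean(k)` with
#' matching-support log-likelihood. The chosen model has the lower
#' small-sample AIC (both models have one parameter, so this is the higher
#' log-likelihood). A scale-free network favours the power law; an
#' Erdős–Rényi random graph favours the Poisson.
#'
#' By default `k_min` is anchored at the minimum positive observed degree:
#' fitting both models on the same observed support is essential because a
#' power law forced to carry probability mass at unobserved small degrees
#' (e.g. k = 1 when every node has k >= 2, as in preferential attachment
#' with m = 2) wastes likelihood and is spuriously rejected.
#'
#' @param degrees Integer vector of node degrees.
#' @param k_min Minimum degree included in the fits; `NULL` (default) uses
#'   the minimum positive observed degree.
#' @return List with `alpha`, `lambda`, `k_min`, per-model log-likelihoods
#'   and AICs, `model` (`"power_law"` or `"poisson"`), and `n` used.
#' @export
classify_degree_model <- function(degrees, k_min = NULL) {
  if (is.null(k_min)) {
    if (!any(degrees > 0)) stop("all degrees are zero", call. = FALSE)
    k_min <- min(degrees[degrees > 0])
  }
  k <- degrees[degrees >= k_min]
  n <- length(k)
  if (n < 10) stop("need at least 10 nodes with degree >= k_min", call. = FALSE)

  # zero-truncated (support >= k_min) Poisson MLE by Newton on the mean
  m <- mean(k)
  lambda <- max(m - k_min + 0.5, 1e-3)
  trunc_mean <- function(l) {
    # mean of Poisson truncated to k >= k_min
    js <- seq_len(k_min) - 1  # 0 .. k_min-1
    (l - sum(stats::dpois(js, l) * js)) / (1 - stats::ppois(k_min - 1, l))
  }
  for (it in 1:100) {
    f <- trunc_mean(lambda) - m
    h <- max(lambda * 1e-6, 1e-9)
    fp <- (trunc_mean(lambda + h) - trunc_mean(lambda - h)) / (2 * h)
    step <- f / fp
    lambda_new <- lambda - step
    if (!is.finite(lambda_new) || lambda_new <= 0) lambda_new <- lambda / 2
    if (abs(lambda_new - lambda) < 1e-10 * (1 + lambda)) { lambda <- lambda_new; break }
    lambda <- lambda_new
  }
  ll_pois <- sum(stats::dpois(k, lambda, log = TRUE)) -
    n * log(1 - stats::ppois(k_min - 1, lambda))

  if (stats::var(k) == 0) {
    warning("all degrees equal: power-law fit is degenerate, returning Poisson",
            call. = FALSE)
    return(list(alpha = NA_real_, lambda = lambda, k_min = k_min,
                loglik_power = NA_real_,
                loglik_poisson = ll_pois, aic_power = NA_real_,
                aic_poisson = 2 - 2 * ll_pois, model = "poisson", n = n))
  }

  alpha <- 1 + n / sum(log(k / (k_min - 0.5)))
  if (!is.finite(alpha) || alpha <= 1 + 1e-9) {
    warning("degenerate power-law fit (alpha <= 1), returning Poisson", call. = FALSE)
    return(list(alpha = alpha, lambda = lambda, k_min = k_min,
                loglik_power = NA_real_,
                loglik_poisson = ll_pois, aic_power = NA_real_,
                aic_poisson = 2 - 2 * ll_pois, model = "poisson", n = n))
  }
  ll_pow <- -alpha * sum(log(k)) - n * log(hurwitz_zeta(alpha, k_min))

  aicc <- function(ll) 2 - 2 * ll + 4 / (n - 2)  # one parameter each
  aic_pow <- aicc(ll_pow)
  aic_pois <- aicc(ll_pois)
  list(alpha = alpha, lambda = lambda, k_min = k_min,
       loglik_power = ll_pow, loglik_poisson = ll_pois,
       aic_power = aic_pow, aic_poisson = aic_pois,
       model = if (aic_pow < aic_pois) "power_law" else "poisson",
       n = n)
}

# Strict third-quartile hub rule on a named degree vector.
hubs_from_degrees <- function(degree) {
  if (length(degree) < 1) stop("empty degree vector", call. = FALSE)
  q3 <- unname(stats::quantile(degree, 0.75, type = 7))
  hubs <- degree[degree > q3]
  list(q3 = q3,
       hubs = tibble::tibble(taxon = names(hubs) %||% as.character(which(degree > q3)),
                             degree = unname(hubs)))
}

#' Identify hub taxa of a co-occurrence network
#'
#' Hubs are nodes whose degree strictly exceeds the third quartile (Q3,
#' linear-interpolation/type-7 quantile) of the network's degree
#' distribution.
#'
#' @param network An `mh_network` with at least 4 nodes, or a named numeric
#'   vector of degrees.
#' @return Object of class `mh_hubs`: list with `q3` and a `hubs` tibble
#'   (`taxon`, `degree`).
#' @export
identify_hubs <- function(network) {
  deg <- if (is.numeric(network)) network else network$degree
  if (length(deg) == 0) stop("empty network has no hubs", call. = FALSE)
  if (length(deg) < 4) stop("need at least 4 nodes to define a third quartile", call. = FALSE)
  structure(hubs_from_degrees(deg), class = "mh_hubs")
}

#' @export
print.mh_hubs <- function(x, ...) {
  cat("Q3(degree) =", x$q3, "->", nrow(x$hubs), "hub taxa\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
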