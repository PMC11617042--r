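test_that("the basis system has the closed-form solution on a 4-taxon example", {
  # t_12 = 1, all other off-diagonals 2: row sums (5, 5, 6, 6);
  # (2I + J) omega^2 = t gives omega^2 = (2/3, 2/3, 7/6, 7/6) and
  # rho_12 = (2/3 + 2/3 - 1) / (2 * 2/3) = 0.25.
  Tm <- matrix(2, 4, 4); diag(Tm) <- 0; Tm[1, 2] <- Tm[2, 1] <- 1
  fit <- solve_basis(Tm)
  expect_equal(unname(fit$omega_sq), c(2/3, 2/3, 7/6, 7/6), tolerance = 1e-12)
  expect_equal(fit$rho[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(diag(fit$rho), rep(1, 4))
  expect_true(all(abs(fit$rho) <= 1))

  # excluding a pair changes the system consistently with the hand algebra:
  # with (1,2) excluded, row 1 reads 2*w1 + w3 + w4 = t13 + t14
  fit2 <- solve_basis(Tm, excluded_pairs = matrix(c(1L, 2L), 1, 2))
  w <- fit2$omega_sq
  expect_equal(unname(2 * w[1] + w[3] + w[4]), Tm[1, 3] + Tm[1, 4], tolerance = 1e-10)
  expect_error(solve_basis(Tm[1:3, 1:3]), "at least 4")
})

test_that("log-ratio variances are scale-invariant and match direct variance", {
  set.seed(19)
  f <- matrix(rgamma(6 * 5, 2), 6, 5)
  f <- f / rowSums(f)
  colnames(f) <- paste0("t", 1:5)
  Tm <- logratio_variances(f)
  expect_equal(Tm[2, 4], var(log(f[, 2] / f[, 4])))
  expect_true(isSymmetric(Tm))
  expect_equal(diag(Tm), setNames(rep(0, 5), colnames(f)))
  # per-sample rescaling leaves every t_ij unchanged
  g <- f * runif(6, 0.1, 10)
  expect_equal(logratio_variances(g), Tm)
  # proportional taxa: zero log-ratio variance
  h <- cbind(f, t6 = 3 * f[, 1])
  expect_equal(logratio_variances(h)["t1", "t6"], 0)
  expect_error(logratio_variances(f[1:2, ]), "at least 3 samples")
  expect_error(logratio_variances(f - 1), "strictly positive")
})

test_that("Dirichlet fraction draws are reproducible, positive and normalized", {
  m <- tiny_counts()
  fr1 <- estimate_fractions(m, n_draws = 3, seed = 7)
  fr2 <- estimate_fractions(m, n_draws = 3, seed = 7)
  expect_identical(fr1, fr2)
  expect_length(fr1, 3)
  expect_true(all(fr1[[1]] > 0))
  expect_equal(unname(rowSums(fr1[[2]])), rep(1, ncol(m)))
  expect_equal(dim(fr1[[1]]), c(ncol(m), nrow(m)))  # samples x taxa
  expect_error(estimate_fractions(m[1:3, ]), "at least 4 taxa")
})

test_that("correlation recovery: coupled pair found, independent taxa near zero", {
  set.seed(23)
  n <- 60; D <- 12
  latent <- matrix(rnorm(n * D), n, D)
  latent[, 2] <- latent[, 1] * 0.95 + rnorm(n, 0, sqrt(1 - 0.95^2))
  frac <- exp(latent + rep(log(seq(2, 4, length.out = D)), each = n))
  frac <- frac / rowSums(frac)
  counts <- sapply(seq_len(n), function(i) rmultinom(1, 5e4, frac[i, ])[, 1])
  rownames(counts) <- paste0("t", 1:D)
  colnames(counts) <- paste0("s", 1:n)
  rho <- sparcc(counts, n_draws = 10, seed = 29)
  expect_gt(rho["t1", "t2"], 0.6)
  off <- abs(rho[upper.tri(rho)])
  expect_lt(sort(off, decreasing = TRUE)[2], 0.45)  # everything else modest
  expect_true(isSymmetric(rho))
  expect_equal(diag(rho), setNames(rep(1, D), rownames(counts)))

  pv <- sparcc_pvalues(counts, rho, n_perm = 60, seed = 31)
  expect_lt(pv["t1", "t2"], 0.05)
  expect_true(all(pv > 0 & pv <= 1))
  expect_gte(min(pv), 1 / 61)              # add-one floor
  expect_true(isSymmetric(pv))
})

test_that("network construction applies strict thresholds and records signs", {
  taxa <- paste0("t", 1:5)
  rho <- diag(5); dimnames(rho) <- list(taxa, taxa)
  rho["t1", "t2"] <- rho["t2", "t1"] <- 0.41      # passes
  rho["t1", "t3"] <- rho["t3", "t1"] <- -0.50     # passes, negative
  rho["t2", "t3"] <- rho["t3", "t2"] <- 0.40      # fails: not strictly > 0.4
  rho["t4", "t5"] <- rho["t5", "t4"] <- 0.90      # fails on p below
  pv <- matrix(0.01, 5, 5, dimnames = dimnames(rho))
  pv["t4", "t5"] <- pv["t5", "t4"] <- 0.05        # not strictly < 0.05
  net <- build_network(rho, pv)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("t1", "t2", "t3"))  # t4, t5 isolated -> dropped
  expect_equal(sort(net$edges$sign), c(-1L, 1L))
  expect_equal(net$degree[["t1"]], 2)
  net_iso <- build_network(rho, pv, keep_isolated = TRUE)
  expect_setequal(net_iso$nodes, taxa)
  expect_equal(net_iso$degree[["t4"]], 0)
  expect_error(build_network(rho, pv, r_threshold = 1.2), "r_threshold")
})

test_that("topology metrics match hand values on canonical graphs", {
  tri <- matrix(0.9, 3, 3); diag(tri) <- 1
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  p <- matrix(0.001, 3, 3)
  topo <- topology_metrics(build_network(tri, p))
  expect_equal(topo$n_nodes, 3L)
  expect_equal(topo$n_edges, 3L)
  expect_equal(topo$average_degree, 2)
  expect_equal(topo$transitivity, 1)
  expect_equal(topo$mean_local_clustering, 1)

  # star on 4 nodes: hub + 3 leaves, no triangles
  star <- diag(4); dimnames(star) <- list(letters[1:4], letters[1:4])
  star[1, 2:4] <- star[2:4, 1] <- 0.8
  topo2 <- topology_metrics(build_network(star, matrix(0.001, 4, 4)))
  expect_equal(topo2$transitivity, 0)
  expect_equal(topo2$average_degree, 1.5)
  expect_equal(topo2$mean_local_clustering, 0)
  expect_equal(sum(topo2$degree_histogram$count), 4L)

  # path a-b-c
  path <- diag(3); dimnames(path) <- list(letters[1:3], letters[1:3])
  path[1, 2] <- path[2, 1] <- 0.8; path[2, 3] <- path[3, 2] <- 0.8
  topo3 <- topology_metrics(build_network(path, matrix(0.001, 3, 3)))
  expect_equal(topo3$transitivity, 0)
  expect_equal(topo3$mean_local_clustering, 0)
})

test_that("degree-model classification separates the two regimes", {
  # MLE alpha agrees with the closed form on a fixed vector
  k <- c(rep(1L, 5), rep(2L, 4), 3L, 7L, 30L)
  fit <- classify_degree_model(k)
  expect_equal(fit$alpha, 1 + length(k) / sum(log(k / 0.5)), tolerance = 1e-12)
  expect_gt(fit$alpha, 1)

  # zero-truncated Poisson MLE satisfies the mean equation
  set.seed(37)
  kp <- rpois(400, 5); kp <- kp[kp >= 1]
  fitp <- classify_degree_model(kp)
  lam <- fitp$lambda
  expect_equal(lam / (1 - exp(-lam)), mean(kp), tolerance = 1e-6)
  expect_equal(fitp$model, "poisson")

  # power-law degrees prefer the power law
  set.seed(41)
  g <- igraph::sample_pa(300, m = 2, directed = FALSE)
  fit_pl <- classify_degree_model(igraph::degree(g))
  expect_equal(fit_pl$model, "power_law")

  expect_error(classify_degree_model(c(1, 1, 1, 10)), "at least 10")
  expect_warning(cst <- classify_degree_model(rep(3L, 20)), "degenerate")
  expect_equal(cst$model, "poisson")
})

test_that("hub detection uses a strict type-7 third quartile", {
  h <- mucohub:::hubs_from_degrees(
    c(a = 1, b = 1, c = 2, d = 2, e = 3, f = 3, g = 10, h = 12))
  expect_equal(h$q3, 4.75)
  expect_setequal(h$hubs$taxon, c("g", "h"))

  h2 <- mucohub:::hubs_from_degrees(c(a = 1, b = 2, c = 3, d = 100))
  expect_equal(h2$q3, 27.25)
  expect_equal(h2$hubs$taxon, "d")

  # all degrees equal: q3 equals every degree, strict rule -> no hubs
  h3 <- mucohub:::hubs_from_degrees(setNames(rep(4, 6), letters[1:6]))
  expect_equal(nrow(h3$hubs), 0)

  star <- diag(5); dimnames(star) <- list(letters[1:5], letters[1:5])
  star[1, 2:5] <- star[2:5, 1] <- 0.8
  net <- build_network(star, matrix(0.001, 5, 5))
  hub <- identify_hubs(net)
  expect_s3_class(hub, "mh_hubs")
  expect_equal(hub$hubs$taxon, "a")
})
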