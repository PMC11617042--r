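test_that("planted networks have the requested topology, names and signs", {
  g <- generate_planted_network("scale_free", D = 40, param = 2, seed = 3)
  expect_equal(igraph::vcount(g), 40)
  expect_equal(igraph::V(g)$name[1], "taxon_01")
  expect_true(all(igraph::E(g)$sign %in% c(-1L, 1L)))
  # preferential attachment with m = 2 adds 2 edges per node after the first
  expect_lte(igraph::ecount(g), 2 * 39)
  expect_gte(igraph::ecount(g), 39)

  g2 <- generate_planted_network("random", D = 40, param = 0.1, seed = 3)
  expect_false(igraph::is_directed(g2))
  # determinism
  g3 <- generate_planted_network("random", D = 40, param = 0.1, seed = 3)
  expect_identical(igraph::as_edgelist(g2), igraph::as_edgelist(g3))
  expect_error(generate_planted_network("scale_free", D = 10, param = 10), "smaller than D")
  expect_error(generate_planted_network("random", D = 10, param = 1.5), "in \\(0, 1\\)")

  # all-negative edges when prob_negative = 1
  g4 <- generate_planted_network("random", D = 20, param = 0.2,
                                 prob_negative = 1, seed = 5)
  expect_true(all(igraph::E(g4)$sign == -1L))
})

test_that("planted correlation matrices are valid and carry the network", {
  g <- generate_planted_network("scale_free", D = 30, param = 2, seed = 7)
  C <- suppressWarnings(network_to_correlation(g, 0.6))
  expect_equal(diag(C), setNames(rep(1, 30), igraph::V(g)$name))
  expect_true(isSymmetric(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)                          # positive definite
  expect_true(all(abs(C) <= 1 + 1e-12))

  el <- igraph::as_edgelist(g, names = FALSE)
  s <- igraph::E(g)$sign
  planted <- C[el]
  # signs preserved and planted entries clearly separated from background
  expect_true(all(sign(planted) == s))
  free <- !(row(C) == col(C))
  free[el] <- FALSE; free[el[, 2:1]] <- FALSE
  expect_lte(max(abs(C[free])), 0.32 + 1e-9)     # background fill cap
  expect_equal(attr(C, "max_planted_deviation"),
               max(abs(planted - 0.6 * s)))
  expect_gt(min(abs(planted)), max(abs(C[free])))  # edges rank above non-edges

  # empty graph -> identity
  g0 <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(g0)$name <- paste0("t", 1:10)
  C0 <- network_to_correlation(g0, 0.5)
  expect_equal(unname(C0), diag(10), ignore_attr = TRUE)
  expect_error(network_to_correlation(g, 1.2), "in \\(0, 1\\)")
})

test_that("count generation respects depth, fold changes and the latent copula", {
  set.seed(61)
  D <- 12
  C <- diag(D); C[1, 2] <- C[2, 1] <- 0.7
  dimnames(C) <- list(paste0("t", 1:D), paste0("t", 1:D))
  out <- generate_counts(C, log_mean = 2, log_sd = 0.8, n_samples = 50,
                         depth = 5e4, seed = 9)
  expect_equal(unname(colSums(out$counts)), rep(5e4, 50))
  expect_equal(dim(out$latent), c(50, D))
  expect_gt(cor(out$latent[, 1], out$latent[, 2]), 0.5)

  # log2 fold change doubles the expected relative abundance of taxon 1
  fc <- c(2, rep(0, D - 1))
  base <- generate_counts(diag(D), 2, 0.5, 400, 5e4, log2_fc = 0, seed = 11)
  up <- generate_counts(diag(D), 2, 0.5, 400, 5e4, log2_fc = fc, seed = 11)
  ratio <- mean(up$latent[, 1]) - mean(base$latent[, 1])
  expect_equal(ratio, log(2) * 2, tolerance = 0.05)

  expect_warning(generate_counts(diag(D), 2, 0.5, 5, depth = 50, seed = 1),
                 "depth below")
})

test_that("synthetic studies are reproducible with complete, consistent truth", {
  cfg <- synthetic_config(D = 20, n_per_group = 8, depth = 2e4,
                          n_differential = 4, seed = 5)
  s1 <- suppressWarnings(generate_study(cfg))
  s2 <- suppressWarnings(generate_study(cfg))
  expect_identical(abund_matrix(s1$table), abund_matrix(s2$table))
  expect_identical(s1$metadata, s2$metadata)

  expect_equal(nrow(s1$table), 20)
  expect_equal(nrow(s1$metadata), 16)
  expect_equal(levels(s1$metadata$group), c("Ctrl", "HFD"))
  expect_true(all(c("body_weight", "fitc_dextran", "alt") %in% names(s1$metadata)))

  tr <- s1$truth
  expect_setequal(names(tr$networks), c("Ctrl", "HFD"))
  expect_equal(nrow(tr$differential), 4)
  expect_equal(sum(tr$differential$log2_fc > 0), 2)
  # truth hubs match the strict-Q3 rule applied to the planted degrees
  deg <- igraph::degree(tr$networks$Ctrl)
  expect_setequal(tr$hubs$Ctrl$hubs$taxon, names(deg)[deg > quantile(deg, 0.75)])
  # phenotype truth designates the five highest-degree planted taxa
  top5 <- names(deg)[order(deg, decreasing = TRUE)][1:5]
  expect_equal(tr$phenotypes$fitc_dextran$taxa, top5)
  expect_length(tr$phenotypes$fitc_dextran$taxa, 5)
  expect_true(all(tr$phenotypes$fitc_dextran$coef == -1))

  # differential taxa actually shift: planted log2 fc recovered from latent
  up_taxa <- tr$differential$feature_id[tr$differential$log2_fc > 0]
  grp <- s1$metadata$group
  lat <- tr$latent
  shift <- colMeans(lat[grp == "HFD", up_taxa, drop = FALSE]) -
    colMeans(lat[grp == "Ctrl", up_taxa, drop = FALSE])
  expect_true(all(shift > 0))

  # different seeds give different data
  s3 <- suppressWarnings(generate_study(synthetic_config(D = 20, n_per_group = 8,
                                                         depth = 2e4,
                                                         n_differential = 4,
                                                         seed = 6)))
  expect_false(identical(abund_matrix(s1$table), abund_matrix(s3$table)))

  expect_error(synthetic_config(D = 5), "at least 10")
  expect_error(synthetic_config(n_per_group = 2), "at least 5")
})

test_that("phenotypes couple to their designated taxa at matched noise", {
  cfg <- synthetic_config(
    D = 15, n_per_group = 25, depth = 3e4, n_differential = 0,
    phenotypes = list(ph = list(taxa = c("taxon_03"), coef = -2, noise_sd = 0.1)),
    seed = 8)
  st <- suppressWarnings(generate_study(cfg))
  lat <- st$truth$latent[, "taxon_03"]
  expect_lt(cor(lat, st$metadata$ph), -0.9)
  expect_equal(st$truth$phenotypes$ph$noise_sd, 0.1)

  bad <- synthetic_config(
    D = 15, phenotypes = list(ph = list(taxa = "no_such", coef = 1, noise_sd = 1)))
  expect_error(suppressWarnings(generate_study(bad)), "unknown taxa")
})
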