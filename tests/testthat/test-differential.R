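test_that("Mann-Whitney reproduces exact and approximate references", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)          # exact: 2 * 1/choose(6,3)

  # ties or pooled n > 10 fall back to the corrected normal approximation
  set.seed(13)
  a <- rnorm(12); b <- rnorm(12, 1)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  res2 <- mann_whitney(a, b)
  expect_equal(res2$p_value, ref$p.value)
  expect_equal(res2$statistic, unname(ref$statistic))

  res3 <- mann_whitney(c(1, 1, 2), c(2, 3, 4))  # ties force approximation
  ref3 <- suppressWarnings(wilcox.test(c(1, 1, 2), c(2, 3, 4), exact = FALSE))
  expect_equal(res3$p_value, ref3$p.value)
  expect_error(mann_whitney(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment matches the step-up formula and is bounded", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.005, 0.04, 0.2, 0.9)
  q <- bh_adjust(p)
  expect_equal(q, p.adjust(p, "BH"))
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("effect scores are computed on the CPM scale with strict flagging", {
  # 4 vs 4 samples; feature f1 differs hugely on the CPM scale, f2 does not.
  # Depths differ so raw counts would mislead without normalization.
  counts <- rbind(
    f1 = c(100, 101, 99, 102, 1, 2, 3, 0),
    f2 = c(50, 51, 49, 52, 50, 52, 49, 51),
    f3 = c(9850, 9848, 9852, 9846, 9949, 9946, 9948, 9949)
  )
  colnames(counts) <- paste0("s", 1:8)
  counts <- counts %*% diag(c(1, 1, 1, 1, 2, 2, 2, 2))  # double case depth
  colnames(counts) <- paste0("s", 1:8)
  tbl <- abundance_table(counts, kind = "taxa")
  md <- tibble::tibble(sample_id = paste0("s", 1:8),
                       group = factor(rep(c("A", "B"), each = 4)))
  res <- effect_score(tbl, md)
  r1 <- res[res$feature_id == "f1", ]
  # CPM means: A ~ 10050, B ~ 100 -> score = log10(diff + 1) ~ 4
  expect_gt(r1$score, 3.9)
  expect_equal(r1$direction, "A")
  expect_equal(r1$p, 2 / choose(8, 4))    # exact extreme split
  expect_true(r1$differential)
  r2 <- res[res$feature_id == "f2", ]
  expect_false(r2$differential)           # no depth-adjusted difference

  # depth invariance: multiplying one sample's counts changes nothing
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 5
  res2 <- effect_score(abundance_table(counts2, kind = "taxa"), md)
  expect_equal(res2$score, res$score)
  expect_equal(res2$p, res$p)

  # flagging is strict at the threshold
  expect_false(any(effect_score(tbl, md, threshold = r1$score)$differential[1]))
})

test_that("covariate adjustment removes a confounded group effect", {
  set.seed(31)
  n <- 40
  grp <- rep(c("A", "B"), each = n / 2)
  cov <- rnorm(n, ifelse(grp == "A", 0, 3))     # covariate tracks group
  # f1 responds only to the covariate; f2 has a real group effect
  base <- matrix(rexp(6 * n, 1 / 100), 6, n)
  base[1, ] <- 100 * exp(0.8 * cov + rnorm(n, 0, 0.1))
  base[2, ] <- 100 * exp(ifelse(grp == "B", 1.5, 0) + rnorm(n, 0, 0.1))
  counts <- round(base) + 1
  dimnames(counts) <- list(paste0("f", 1:6), paste0("s", 1:n))
  tbl <- abundance_table(counts, kind = "taxa")
  md <- tibble::tibble(sample_id = colnames(counts), group = factor(grp),
                       bw = cov)
  adj <- covariate_adjusted_association(tbl, md, covariate = "bw")
  raw <- covariate_adjusted_association(
    tbl, dplyr::mutate(md, bw = bw * 0 + seq_len(n) * 1e-9 + rnorm(n)), "bw")
  expect_gt(adj$p[adj$feature_id == "f1"], 0.05)   # confound absorbed
  expect_lt(adj$p[adj$feature_id == "f2"], 0.01)   # true effect survives
  expect_lt(raw$p[raw$feature_id == "f1"], 0.01)   # unadjusted model is fooled

  # agreement with stats::lm on one feature
  rel <- sweep(counts, 2, colSums(counts), "/")
  x <- rel["f2", ]
  y <- log(x + min(x[x > 0]) / 2)
  fit <- summary(lm(y ~ factor(grp) + cov))
  expect_equal(adj$estimate[adj$feature_id == "f2"],
               unname(coef(fit)[2, 1]), tolerance = 1e-10)
  expect_equal(adj$p[adj$feature_id == "f2"],
               unname(coef(fit)[2, 4]), tolerance = 1e-10)

  # constant covariate: warned and dropped, not an error
  md0 <- dplyr::mutate(md, bw = 1)
  expect_warning(res0 <- covariate_adjusted_association(tbl, md0, "bw"),
                 "constant covariate")
  expect_equal(nrow(res0), 6)
})

test_that("differential_analysis joins screen and adjusted model per feature", {
  tbl <- tiny_table(n_taxa = 6, n_samples = 10, seed = 17)
  md <- tiny_metadata(10)
  res <- differential_analysis(tbl, md, covariate = "body_weight")
  expect_setequal(names(res), c("feature_id", "direction", "p", "q", "score",
                                "differential", "coef", "coef_p", "coef_q"))
  expect_equal(res$feature_id, tbl$feature_id)
  res_no_cov <- differential_analysis(tbl, md)
  expect_false("coef" %in% names(res_no_cov))
})
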