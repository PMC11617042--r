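# Group-difference screening: rank tests, LDA-style effect scores on the
# counts-per-million scale, covariate-adjusted per-feature linear models,
# and Benjamini-Hochberg adjustment.

#' Mann-Whitney U test
#'
#' Exact enumeration p-value when the pooled sample size is at most 10 and
#' there are no ties; tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @return List with `statistic` (U for the first group) and `p_value`
#'   (two-sided).
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  pooled <- c(values_a, values_b)
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- length(pooled) <= 10 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; monotone in the ranked
#' p-values and never smaller than the input p.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Counts-per-million normalization, features x samples.
cpm <- function(m) sweep(m, 2, colSums(m), "/") * 1e6

#' Rank-test screening with LDA-style effect scores
#'
#' Features are normalized to counts per million (CPM) within each sample so
#' scores are invariant to sequencing depth. Each feature is screened by a
#' two-sided Mann-Whitney test between groups; features passing the screen
#' (`p < alpha`) receive the effect size
#' `score = log10(|mean_A - mean_B| + 1)` on the CPM scale together with the
#' direction of enrichment. Features with `score > threshold` (default 1.5,
#' the published cutoff) and a passing screen are flagged as differential.
#'
#' @param table An abundance table tibble.
#' @param metadata Metadata tibble aligned by sample id.
#' @param alpha Screening significance level.
#' @param threshold Effect-score cutoff (log10 CPM-difference scale).
#' @param group_col Metadata column holding the two-level group factor.
#' @return Tibble with `feature_id`, `direction`, `p`, `q`, `score`,
#'   `differential`.
#' @export
effect_score <- function(table, metadata, alpha = 0.05, threshold = 1.5,
                         group_col = "group") {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  al <- align_samples(table, metadata)
  m <- cpm(abund_matrix(al$table))
  grp <- factor(al$metadata[[group_col]])
  lev <- levels(grp)
  a_idx <- grp == lev[1]
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    xa <- m[i, a_idx]
    xb <- m[i, !a_idx]
    p <- mann_whitney(xa, xb)$p_value
    diff_means <- mean(xa) - mean(xb)
    tibble::tibble(
      feature_id = rownames(m)[i],
      direction = ifelse(diff_means >= 0, lev[1], lev[2]),
      p = p,
      score = log10(abs(diff_means) + 1)
    )
  })
  res$q <- bh_adjust(res$p)
  res$differential <- res$p < alpha & res$score > threshold
  res[, c("feature_id", "direction", "p", "q", "score", "differential")]
}

#' Covariate-adjusted per-feature association with group
#'
#' For each feature, relative abundances (total-sum scaling) are
#' log-transformed with a pseudocount equal to half that feature's smallest
#' nonzero relative abundance, then regressed by ordinary least squares on
#' the group indicator plus one numeric covariate. The group coefficient is
#' tested two-sided (t distribution) and BH-adjusted across features.
#'
#' @inheritParams effect_score
#' @param covariate Name of a numeric metadata column (e.g. body weight).
#' @return Tibble with `feature_id`, `estimate` (group coefficient), `p`, `q`.
#' @export
covariate_adjusted_association <- function(table, metadata, covariate,
                                           group_col = "group") {
  al <- align_samples(table, metadata)
  if (!covariate %in% names(al$metadata)) {
    stop("covariate '", covariate, "' not found in metadata", call. = FALSE)
  }
  cov <- al$metadata[[covariate]]
  if (!is.numeric(cov)) stop("covariate must be numeric", call. = FALSE)
  grp <- factor(al$metadata[[group_col]])
  use_cov <- TRUE
  if (stats::var(cov) == 0) {
    warning("constant covariate '", covariate, "' dropped from the model", call. = FALSE)
    use_cov <- FALSE
  }
  m <- abund_matrix(al$table)
  rel <- sweep(m, 2, colSums(m), "/")
  X <- if (use_cov) stats::model.matrix(~ grp + cov) else stats::model.matrix(~ grp)
  res <- purrr::map_dfr(seq_len(nrow(rel)), function(i) {
    x <- rel[i, ]
    if (stats::var(x) == 0) {
      return(tibble::tibble(feature_id = rownames(rel)[i], estimate = 0, p = 1))
    }
    pseudo <- min(x[x > 0]) / 2
    y <- log(x + pseudo)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - fit$rank
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(diag(XtXinv) * rss / df)
    beta <- fit$coefficients[2]
    p <- if (se[2] == 0) {
      if (beta == 0) 1 else .Machine$double.xmin
    } else {
      2 * stats::pt(-abs(beta / se[2]), df)
    }
    tibble::tibble(feature_id = rownames(rel)[i], estimate = unname(beta),
                   p = max(p, .Machine$double.xmin))
  })
  res$q <- bh_adjust(res$p)
  res
}

#' Combined differential-abundance analysis
#'
#' Joins the rank-test/effect-score screen with the covariate-adjusted
#' linear-model coefficients into one per-feature table.
#'
#' @inheritParams covariate_adjusted_association
#' @inheritParams effect_score
#' @return Tibble with `feature_id`, `direction`, `p`, `q`, `score`,
#'   `differential`, and (when `covariate` is given) `coef`, `coef_p`,
#'   `coef_q`.
#' @export
differential_analysis <- function(table, metadata, covariate = NULL,
                                  alpha = 0.05, threshold = 1.5,
                                  group_col = "group") {
  res <- effect_score(table, metadata, alpha = alpha, threshold = threshold,
                      group_col = group_col)
  if (!is.null(covariate)) {
    adj <- covariate_adjusted_association(table, metadata, covariate,
                                          group_col = group_col)
    names(adj) <- c("feature_id", "coef", "coef_p", "coef_q")
    res <- dplyr::left_join(res, adj, by = "feature_id")
  }
  res
}
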