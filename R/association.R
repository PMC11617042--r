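# Rank-correlation of taxa with host phenotypes or pathway abundances.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Mid-ranks are used for ties; the p-value comes from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom, with
#' `p = 0` by convention when `rho = +-1`. A constant input yields
#' `rho = 0`, `p = 1` and `constant = TRUE`. For `n <= 8` an exact
#' permutation p-value over all n! orderings is available.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param exact Use exact permutation enumeration (only for `n <= 8`)?
#' @return List with `rho`, `p_value`, `constant`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = 0, p_value = 1, constant = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    return(list(rho = sign(rho), p_value = 0, constant = FALSE))
  }
  if (exact) {
    if (n > 8) stop("exact enumeration only supported for n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    obs <- abs(rho)
    hits <- sum(apply(perms, 1, function(idx) abs(stats::cor(rx, ry[idx])) >= obs - 1e-12))
    return(list(rho = rho, p_value = hits / nrow(perms), constant = FALSE))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), n - 2), constant = FALSE)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Associate taxa with phenotype variables or pathway abundances
#'
#' Computes all-pairs Spearman correlations between the CPM-normalized
#' abundances of selected taxa and either numeric metadata phenotype columns
#' or the features of a second (pathway) abundance table, with BH adjustment
#' across the whole association table. Because the statistic is rank-based,
#' any monotone per-sample normalization of the taxa gives identical rho.
#'
#' @param table Taxon abundance table tibble.
#' @param metadata Metadata tibble (used for phenotype `variables` and for
#'   sample alignment).
#' @param taxa Character vector of taxa to test (default: all features).
#' @param variables Character vector of numeric metadata columns (default:
#'   all numeric columns except the group column).
#' @param pathways Optional second abundance table whose features are used
#'   as variables instead of metadata columns.
#' @param group_col Metadata group column name (excluded from variables).
#' @param alpha Significance level for the `significant` flag (raw p).
#' @return Long tibble: `taxon`, `variable`, `rho`, `p`, `q`, `significant`.
#' @export
associate <- function(table, metadata, taxa = NULL, variables = NULL,
                      pathways = NULL, group_col = "group", alpha = 0.05) {
  al <- align_samples(table, metadata)
  m <- cpm(abund_matrix(al$table))
  if (is.null(taxa)) taxa <- rownames(m)
  unknown <- setdiff(taxa, rownames(m))
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(pathways)) {
    alp <- align_samples(pathways, al$metadata)
    vm <- cpm(abund_matrix(alp$table))
    vm <- vm[, colnames(m), drop = FALSE]
    if (is.null(variables)) variables <- rownames(vm)
    unknown <- setdiff(variables, rownames(vm))
    if (length(unknown)) stop("unknown pathways: ", paste(unknown, collapse = ", "), call. = FALSE)
    var_get <- function(v) vm[v, ]
  } else {
    numeric_cols <- names(al$metadata)[vapply(al$metadata, is.numeric, TRUE)]
    if (is.null(variables)) variables <- setdiff(numeric_cols, group_col)
    unknown <- setdiff(variables, numeric_cols)
    if (length(unknown)) stop("unknown variables: ", paste(unknown, collapse = ", "), call. = FALSE)
    var_get <- function(v) al$metadata[[v]]
  }
  res <- tidyr::expand_grid(taxon = taxa, variable = variables)
  stats_list <- purrr::map2(res$taxon, res$variable, function(tx, v) {
    spearman_cor(m[tx, ], var_get(v))
  })
  res$rho <- purrr::map_dbl(stats_list, "rho")
  res$p <- purrr::map_dbl(stats_list, "p_value")
  res$q <- bh_adjust(res$p)
  res$significant <- res$p < alpha
  res
}
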