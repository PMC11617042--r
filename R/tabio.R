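# Tabular and graph I/O with identity/shape validation.
#
# Abundance tables travel as tibbles whose first column ("feature_id") holds
# taxon or pathway identifiers and whose remaining columns are samples.
# Metadata travels as a tibble keyed by "sample_id". Everything is TSV
# (tab-separated, UTF-8, '.' decimal) so artifacts are diff-friendly.

#' Validate and construct an abundance table
#'
#' An abundance table is a tibble whose first column (`feature_id`) contains
#' unique feature identifiers (taxa or pathways, treated as opaque strings)
#' and whose remaining columns are per-sample abundances. Taxon tables must
#' hold non-negative integer counts; pathway tables may hold non-negative
#' reals.
#'
#' @param x A data frame (first column feature ids) or a numeric matrix with
#'   row names (features) and column names (samples).
#' @param kind `"taxa"` (integer counts) or `"pathway"` (non-negative reals).
#' @return A tibble of class `mh_abund` with attribute `kind`.
#' @export
abundance_table <- function(x, kind = c("taxa", "pathway")) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input needs feature row names and sample column names", call. = FALSE)
    }
    x <- tibble::as_tibble(x, rownames = "feature_id")
  }
  x <- tibble::as_tibble(x)
  names(x)[1] <- "feature_id"
  feats <- as.character(x$feature_id)
  samples <- names(x)[-1]
  if (anyDuplicated(feats)) {
    stop("duplicate feature identifiers: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 features", call. = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric or missing abundance values", call. = FALSE)
  if (any(m < 0)) stop("negative abundance values are not allowed", call. = FALSE)
  if (kind == "taxa" && any(abs(m - round(m)) > 1e-8)) {
    stop("taxon tables must contain integer counts", call. = FALSE)
  }
  x$feature_id <- feats
  out <- structure(x, kind = kind)
  class(out) <- c("mh_abund", class(tibble::tibble()))
  out
}

#' Read an abundance table from TSV
#'
#' Expects a header row of sample identifiers with feature identifiers in the
#' first column. Input feature order is preserved.
#'
#' @param path Path to a TSV file.
#' @inheritParams abundance_table
#' @return A validated [abundance_table()] tibble.
#' @export
read_abundance_table <- function(path, kind = c("taxa", "pathway")) {
  kind <- match.arg(kind)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    stop("duplicate sample identifiers in header of ", path, call. = FALSE)
  }
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = c("character", rep("numeric", length(header) - 1L)))
  abundance_table(tibble::as_tibble(x), kind = kind)
}

#' Write an abundance table to TSV
#'
#' @param x An abundance table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Extract the features-by-samples numeric matrix of an abundance table
#'
#' @param x An abundance table tibble (first column feature ids).
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
abund_matrix <- function(x) {
  m <- as.matrix(tibble::as_tibble(x)[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read and validate per-sample study metadata
#'
#' The metadata TSV must contain a `sample_id` column and a two-level group
#' column (each level with at least 2 samples); all other columns are
#' numeric covariates or phenotypes.
#'
#' @param path Path to a TSV file.
#' @param group_col Name of the group column (default `"group"`).
#' @return A validated tibble; the group column is a factor with 2 levels.
#' @export
read_metadata <- function(path, group_col = "group") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(x, group_col)
}

#' Validate a study metadata table
#'
#' @param x Data frame with `sample_id`, a group column and numeric columns.
#' @inheritParams read_metadata
#' @return The validated tibble.
#' @export
validate_metadata <- function(x, group_col = "group") {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) stop("metadata needs a 'sample_id' column", call. = FALSE)
  if (!group_col %in% names(x)) stop("metadata is missing group column '", group_col, "'", call. = FALSE)
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  g <- factor(x[[group_col]])
  if (nlevels(g) != 2L) {
    stop("group column '", group_col, "' must have exactly 2 levels, found ",
         nlevels(g), call. = FALSE)
  }
  if (any(table(g) < 2L)) stop("both group levels need at least 2 samples", call. = FALSE)
  x[[group_col]] <- g
  num_cols <- setdiff(names(x), c("sample_id", group_col))
  for (cl in num_cols) {
    if (!is.numeric(x[[cl]])) {
      stop("metadata column '", cl, "' must be numeric", call. = FALSE)
    }
  }
  x
}

#' Align an abundance table with study metadata by sample id
#'
#' Alignment is always by identifier, never by column position. Samples in
#' the table that are missing from the metadata are an error; metadata rows
#' without a matching sample are dropped with a warning.
#'
#' @param table An abundance table tibble.
#' @param metadata A validated metadata tibble.
#' @return A list with the table (unchanged) and the metadata reordered to
#'   the table's sample order.
#' @export
align_samples <- function(table, metadata) {
  samples <- names(table)[-1]
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(metadata$sample_id, samples)
  if (length(extra)) {
    warning("dropping ", length(extra), " metadata sample(s) not present in the table",
            call. = FALSE)
  }
  metadata <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  list(table = table, metadata = metadata)
}

#' Write a co-occurrence network to disk
#'
#' The edge-list format is a TSV with columns `source`, `target`, `rho`,
#' `p`, `sign`; GML carries the same attributes. Re-reading an edge list
#' with [read_network()] reproduces the edge set exactly.
#'
#' @param network A network from [build_network()].
#' @param path Output path.
#' @param format `"edgelist"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    readr::write_tsv(network$edges, path)
  } else {
    igraph::write_graph(network$graph, path, format = "gml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to an edge-list TSV.
#' @return A network object of class `mh_network` (see [build_network()]).
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             source = readr::col_character(),
                             target = readr::col_character(),
                             rho = readr::col_double(),
                             p = readr::col_double(),
                             sign = readr::col_integer()
                           ))
  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  new_network(g, edges)
}
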