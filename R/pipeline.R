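# End-to-end orchestration: community -> differential -> per-group network
# inference -> association, with all artifacts written as TSV/GML/JSON.

#' Median and IQR per group with a Mann-Whitney p-value
#'
#' Quartiles use the same linear-interpolation (type-7) convention as hub
#' detection.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping aligned with `values`.
#' @return List with `by_group` (tibble: group, n, median, q1, q3) and
#'   `p_value` from [mann_whitney()].
#' @export
summarize_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  by_group <- purrr::map_dfr(levels(groups), function(lev) {
    v <- values[groups == lev]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    tibble::tibble(group = lev, n = length(v),
                   median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]))
  })
  p <- mann_whitney(values[groups == levels(groups)[1]],
                    values[groups == levels(groups)[2]])$p_value
  list(by_group = by_group, p_value = p)
}

#' Run configuration for the full pipeline
#'
#' Either a synthetic study config or paths to existing tables.
#'
#' @param synthetic An [synthetic_config()] (used when no input paths given).
#' @param table_path,metadata_path Optional TSV inputs for a real study.
#' @param r_threshold,p_threshold Network edge thresholds.
#' @param lda_threshold,alpha Differential screening thresholds.
#' @param n_perm Correlation permutation count.
#' @param n_draws Dirichlet draws for the correlation estimate.
#' @param permanova_perm PERMANOVA permutations.
#' @param covariate Metadata column adjusted for in the per-feature models
#'   (NULL to skip).
#' @param seed Master seed.
#' @return List of class `mh_run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       table_path = NULL, metadata_path = NULL,
                       r_threshold = 0.4, p_threshold = 0.05,
                       lda_threshold = 1.5, alpha = 0.05,
                       n_perm = 100, n_draws = 20, permanova_perm = 999,
                       covariate = "body_weight", seed = 1) {
  stopifnot(r_threshold > 0, r_threshold < 1, p_threshold > 0, p_threshold < 1,
            lda_threshold > 0, alpha > 0, alpha < 1)
  structure(list(synthetic = synthetic, table_path = table_path,
                 metadata_path = metadata_path,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 lda_threshold = lda_threshold, alpha = alpha,
                 n_perm = n_perm, n_draws = n_draws,
                 permanova_perm = permanova_perm,
                 covariate = covariate, seed = seed),
            class = "mh_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: alpha diversity with per-group summaries, Bray-Curtis
#' PCoA, PERMANOVA, differential screening (with covariate adjustment),
#' per-group co-occurrence network inference with topology metrics and hub
#' detection (networks are inferred within each group's samples only), and
#' Spearman association of the differential and hub taxa with the phenotype
#' columns. All artifacts are written under `out_dir` (TSV tables, edge-list
#' and GML networks, JSON summaries) plus a JSON run report. Deterministic
#' given the config seed: rerunning writes byte-identical tables.
#'
#' @param config An [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return The run report (list, class `mh_report`), invisibly containing
#'   all in-memory results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "mh_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  unlink(log_path)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message("[mucohub] ", ...)
  }
  files <- character()
  put <- function(name) {
    files[[length(files) + 1]] <<- file.path(out_dir, name)
    file.path(out_dir, name)
  }

  stage <- "input"
  report <- tryCatch({
    if (!is.null(config$table_path)) {
      say("reading tables")
      table <- read_abundance_table(config$table_path)
      metadata <- read_metadata(config$metadata_path)
      truth <- NULL
    } else {
      say("generating synthetic study (seed ", config$synthetic$seed, ")")
      study <- generate_study(config$synthetic)
      table <- study$table
      metadata <- study$metadata
      truth <- study$truth
      write_abundance_table(table, put("counts.tsv"))
      readr::write_tsv(metadata, put("metadata.tsv"))
    }
    al <- align_samples(table, metadata)
    table <- al$table
    metadata <- al$metadata
    groups <- factor(metadata$group)

    stage <- "community"
    say("alpha/beta diversity")
    alpha_tbl <- alpha_diversity(table)
    readr::write_tsv(alpha_tbl, put("alpha_diversity.tsv"))
    div_summary <- lapply(c(shannon = "shannon", simpson = "simpson"), function(cl) {
      s <- summarize_groups(alpha_tbl[[cl]], groups)
      list(by_group = s$by_group, p_value = s$p_value)
    })
    d <- bray_curtis(table)
    ord <- pcoa(d)
    readr::write_tsv(ord$coordinates, put("pcoa_coordinates.tsv"))
    permanova_seed <- make_seed(config$seed, 101)
    say("permanova (seed ", permanova_seed, ")")
    perm <- permanova(d, groups, n_perm = config$permanova_perm,
                      seed = permanova_seed)
    jsonlite::write_json(
      list(pseudo_F = perm$statistic, p_value = perm$p_value,
           n_perm = perm$n_perm),
      put("permanova.json"), auto_unbox = TRUE, digits = NA)

    stage <- "differential"
    say("differential screening")
    covariate <- config$covariate
    if (!is.null(covariate) && !covariate %in% names(metadata)) covariate <- NULL
    diff_tbl <- differential_analysis(table, metadata, covariate = covariate,
                                      alpha = config$alpha,
                                      threshold = config$lda_threshold)
    readr::write_tsv(diff_tbl, put("differential.tsv"))

    stage <- "netinfer"
    networks <- list()
    topologies <- list()
    hubsets <- list()
    for (lev in levels(groups)) {
      rho_seed <- make_seed(config$seed, 201 + match(lev, levels(groups)))
      perm_seed <- make_seed(config$seed, 301 + match(lev, levels(groups)))
      say("network inference: ", lev,
          " (sparcc seed ", rho_seed, ", permutation seed ", perm_seed, ")")
      sub <- table[, c(TRUE, groups == lev)]
      rho <- sparcc(sub, n_draws = config$n_draws, seed = rho_seed)
      pv <- sparcc_pvalues(sub, rho, n_perm = config$n_perm, seed = perm_seed)
      net <- build_network(rho, pv, r_threshold = config$r_threshold,
                           p_threshold = config$p_threshold)
      write_network(net, put(paste0("network_", lev, ".tsv")), "edgelist")
      write_network(net, put(paste0("network_", lev, ".gml")), "gml")
      topo <- topology_metrics(net)
      hubs <- if (length(net$degree) >= 4) identify_hubs(net) else NULL
      jsonlite::write_json(
        list(topology = unclass(generics::glance(topo)),
             q3 = hubs$q3, hubs = hubs$hubs),
        put(paste0("topology_", lev, ".json")), auto_unbox = TRUE, digits = NA)
      networks[[lev]] <- net
      topologies[[lev]] <- topo
      hubsets[[lev]] <- hubs
    }

    stage <- "association"
    say("phenotype association")
    hub_taxa <- unique(unlist(lapply(hubsets, function(h) h$hubs$taxon)))
    focus <- unique(c(diff_tbl$feature_id[diff_tbl$differential], hub_taxa))
    phen_cols <- setdiff(names(metadata)[vapply(metadata, is.numeric, TRUE)],
                         c(config$covariate))
    assoc <- if (length(focus) && length(phen_cols)) {
      associate(table, metadata, taxa = focus, variables = phen_cols)
    } else {
      tibble::tibble(taxon = character(), variable = character(),
                     rho = numeric(), p = numeric(), q = numeric(),
                     significant = logical())
    }
    readr::write_tsv(assoc, put("association.tsv"))

    stage <- "report"
    report <- list(
      seed = config$seed,
      thresholds = list(r = config$r_threshold, p = config$p_threshold,
                        lda = config$lda_threshold, alpha = config$alpha),
      config_hash = rlang::hash(config),
      diversity = div_summary,
      permanova = list(pseudo_F = perm$statistic, p_value = perm$p_value),
      n_differential = sum(diff_tbl$differential),
      networks = lapply(topologies, function(t) unclass(generics::glance(t))),
      hubs = lapply(hubsets, function(h) if (is.null(h)) NULL else h$hubs$taxon),
      files = basename(unlist(files))
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    structure(c(report,
                list(results = list(alpha = alpha_tbl, ordination = ord,
                                    permanova = perm, differential = diff_tbl,
                                    networks = networks, topologies = topologies,
                                    hubs = hubsets, association = assoc,
                                    truth = truth))),
              class = "mh_report")
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  say("done")
  invisible(report)
}

#' @export
print.mh_report <- function(x, ...) {
  cat("mucohub run (seed ", x$seed, "): PERMANOVA p = ",
      signif(x$permanova$p_value, 3), ", ", x$n_differential,
      " differential taxa, networks: ",
      paste(names(x$networks), collapse = ", "), "\n", sep = "")
  invisible(x)
}
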