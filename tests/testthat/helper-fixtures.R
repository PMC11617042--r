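# Shared fixtures: everything is built in code at test time.

# A small counts matrix with taxon/sample names.
tiny_counts <- function(n_taxa = 5, n_samples = 6, seed = 42, depth = 1000) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_taxa * n_samples, depth / n_taxa),
              n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  m
}

tiny_table <- function(...) abundance_table(tiny_counts(...), kind = "taxa")

tiny_metadata <- function(n_samples = 6, seed = 7) {
  set.seed(seed)
  tibble::tibble(
    sample_id = paste0("s", seq_len(n_samples)),
    group = factor(rep(c("Ctrl", "HFD"), length.out = n_samples)),
    body_weight = stats::rnorm(n_samples, 25, 2),
    fitc = stats::rnorm(n_samples)
  )
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
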