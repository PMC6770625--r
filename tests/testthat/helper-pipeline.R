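# Shared pipeline runs, computed once per test session.

.run_cache <- new.env(parent = emptyenv())

# full run at the reference study conditions (the sim_config defaults)
default_run <- function() {
  if (!is.null(.run_cache$default)) return(.run_cache$default)
  out <- file.path(tempdir(), "retrospect-default-run")
  cfg <- run_config(seed = 1, outdir = out)
  cfg <- suppressWarnings(suppressMessages(run_stage("run-all", cfg)))
  truth_genes <- read_scores_tsv(file.path(out, "sim", "truth_genes.tsv"))
  truth_sets <- read_scores_tsv(file.path(out, "sim", "truth_sets.tsv"))
  .run_cache$default <- list(cfg = cfg, outdir = out,
                             truth_genes = truth_genes,
                             truth_sets = truth_sets)
  .run_cache$default
}

# small configuration for fast structural tests
small_sim_overrides <- function() {
  list(n_genes = 150L, n_chromosomes = 2L,
       planted_enriched = list(count = 12L, fraction = 0.8),
       planted_deficient = list(count = 12L, fraction = 0.05),
       n_pathways = 20L, n_planted_pathways = 3L,
       n_terms = 12L, n_planted_terms = 3L,
       category_example_size = 25L,
       tags_per_gene_mean = 25)
}

small_run <- function() {
  if (!is.null(.run_cache$small)) return(.run_cache$small)
  out <- file.path(tempdir(), "retrospect-small-run")
  cfg <- run_config(seed = 42, outdir = out,
                    marks = c(mA1 = "active", mA2 = "active",
                              mR1 = "repressive"),
                    cell_lines = c("L1", "L2"),
                    simulate = small_sim_overrides())
  cfg <- suppressWarnings(suppressMessages(run_stage("run-all", cfg)))
  .run_cache$small <- list(cfg = cfg, outdir = out)
  .run_cache$small
}
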