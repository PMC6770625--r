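test_that("config validation enforces the planted-fraction ordering", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(1, background_re_fraction = 0.9),
               "planted_enriched")
  expect_error(sim_config(1, planted_deficient = list(count = 10, fraction = 0.3)),
               "planted_enriched")
  expect_error(sim_config(1, n_genes = 150,
                          planted_enriched = list(count = 100, fraction = 0.8),
                          planted_deficient = list(count = 60, fraction = 0.05)),
               "exceed")
  cfg <- sim_config(7, n_genes = 100,
                    planted_enriched = list(count = 10, fraction = 0.8),
                    planted_deficient = list(count = 10, fraction = 0.05))
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 7L)
})

test_that("sim config round-trips through YAML", {
  cfg <- sim_config(3, n_genes = 80, tags_per_gene_mean = 12,
                    planted_enriched = list(count = 8, fraction = 0.8),
                    planted_deficient = list(count = 8, fraction = 0.05))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$n_genes, 80)
  expect_equal(back$tags_per_gene_mean, 12)
  expect_equal(back$marks, cfg$marks)
  writeLines(c("seed: 1", "no_such_key: 2"), f)
  expect_error(read_sim_config(f), "unknown config key")
})

test_that("identical seeds give byte-identical file sets, different seeds differ", {
  cfg <- do.call(sim_config, c(list(seed = 99), small_sim_overrides()))
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  suppressMessages(simulate_dataset(cfg, d1))
  suppressMessages(simulate_dataset(cfg, d2))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  cfg2 <- do.call(sim_config, c(list(seed = 100), small_sim_overrides()))
  d3 <- file.path(withr::local_tempdir(), "c")
  suppressMessages(simulate_dataset(cfg2, d3))
  expect_false(identical(tools::md5sum(file.path(d1, "genes.bed"))[[1]],
                         tools::md5sum(file.path(d3, "genes.bed"))[[1]]))
})

test_that("outputs parse, carry the seed header, and respect the layout", {
  run <- small_run()
  sim <- file.path(run$outdir, "sim")
  genes <- read_gene_table(file.path(sim, "genes.bed"), "bed6")
  expect_equal(nrow(genes), 150)
  expect_true(all(genes$strand %in% c("+", "-")))
  reps <- read_repeat_table(file.path(sim, "repeats.bed"),
                            "bed6_class_in_name")
  expect_setequal(unique(reps$re_class), c("SINE", "LINE", "LTR_ERV"))
  expect_equal(readLines(file.path(sim, "genes.bed"), n = 1), "# seed=42")
  # TSS neighborhoods are pairwise disjoint by construction
  nb <- tss_neighborhood(genes)
  o <- order(nb$chrom, nb$start)
  same <- nb$chrom[o][-1] == nb$chrom[o][-nrow(nb)]
  expect_true(all(nb$start[o][-1][same] >= nb$end[o][-nrow(nb)][same]))
})

test_that("empirical RE-linked fractions recover the planted fractions", {
  ov <- small_sim_overrides()
  ov$n_genes <- 400L
  ov$planted_enriched <- list(count = 60L, fraction = 0.8)
  ov$tags_per_gene_mean <- 40
  cfg <- do.call(sim_config, c(list(seed = 5, cell_lines = "L1",
                                    marks = c(m1 = "active")), ov))
  d <- withr::local_tempdir()
  man <- suppressMessages(simulate_dataset(cfg, d))
  genes <- read_gene_table(file.path(d, "genes.bed"), "bed6")
  reps <- read_repeat_table(file.path(d, "repeats.bed"), "bed6_class_in_name")
  tags <- read_tag_bed(file.path(d, "tags_m1_L1.bed"), "m1", "L1")
  ths <- count_total_hits(genes, tags)
  hes <- count_re_linked_hits(genes, tags, reps)
  truth <- man$truth_genes
  frac <- ifelse(ths > 0, hes / ths, NA)
  for (st in c("enriched", "background", "deficient")) {
    ids <- truth$gene_id[truth$status == st]
    emp <- mean(frac[ids], na.rm = TRUE)
    expect_lt(abs(emp - truth$re_fraction[truth$status == st][1]), 0.05,
              label = paste("fraction error for", st))
  }
})

test_that("fraction estimates tighten with sequencing depth", {
  ov <- small_sim_overrides()
  ov$n_genes <- 200L
  err <- vapply(c(10, 80), function(depth) {
    ov$tags_per_gene_mean <- depth
    cfg <- do.call(sim_config, c(list(seed = 8, cell_lines = "L1",
                                      marks = c(m1 = "active")), ov))
    d <- withr::local_tempdir()
    man <- suppressMessages(simulate_dataset(cfg, d))
    genes <- read_gene_table(file.path(d, "genes.bed"), "bed6")
    reps <- read_repeat_table(file.path(d, "repeats.bed"),
                              "bed6_class_in_name")
    tags <- read_tag_bed(file.path(d, "tags_m1_L1.bed"), "m1", "L1")
    ths <- count_total_hits(genes, tags)
    hes <- count_re_linked_hits(genes, tags, reps)
    frac <- ifelse(ths > 0, hes / ths, NA)
    mean(abs(frac - man$truth_genes$re_fraction), na.rm = TRUE)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("null mode removes the planted/background contrast", {
  ov <- small_sim_overrides()
  ov$planted_enriched <- list(count = 12L, fraction = 0.2000001)
  ov$planted_deficient <- list(count = 12L, fraction = 0.1999999)
  cfg <- do.call(sim_config, c(list(seed = 13, cell_lines = "L1",
                                    marks = c(m1 = "active")), ov))
  d <- withr::local_tempdir()
  man <- suppressMessages(simulate_dataset(cfg, d))
  expect_setequal(unique(man$truth_genes$status),
                  c("enriched", "deficient", "background"))
  genes <- read_gene_table(file.path(d, "genes.bed"), "bed6")
  reps <- read_repeat_table(file.path(d, "repeats.bed"), "bed6_class_in_name")
  tags <- read_tag_bed(file.path(d, "tags_m1_L1.bed"), "m1", "L1")
  ths <- count_total_hits(genes, tags)
  hes <- count_re_linked_hits(genes, tags, reps)
  tr <- man$truth_genes
  f_enr <- sum(hes[tr$gene_id[tr$status == "enriched"]]) /
    sum(ths[tr$gene_id[tr$status == "enriched"]])
  f_bg <- sum(hes[tr$gene_id[tr$status == "background"]]) /
    sum(ths[tr$gene_id[tr$status == "background"]])
  expect_equal(f_enr, f_bg, tolerance = 0.06)
})

test_that("expression couples to mark totals with configurable noise", {
  cfg <- sim_config(21, n_genes = 300,
                    marks = c(act = "active", rep = "repressive"),
                    cell_lines = "L1",
                    expression_noise_sd = 0,
                    expression_coupling = c(active = 1, repressive = 0))
  ths <- array(rpois(300 * 2, 30), dim = c(300, 2, 1),
               dimnames = list(sprintf("g%03d", 1:300), c("act", "rep"),
                               "L1"))
  e <- make_expression(cfg, ths)
  expect_equal(cor(e[, 1], ths[, "act", 1], method = "spearman"), 1)
  # sign flip of couplings flips the correlation sign
  cfg2 <- cfg
  cfg2$expression_coupling <- c(active = -1, repressive = 0)
  e2 <- make_expression(cfg2, ths)
  expect_equal(e2[, 1], -e[, 1])
  # zero couplings: pure noise, negligible correlation at n = 300
  cfg3 <- cfg
  cfg3$expression_coupling <- c(active = 0, repressive = 0)
  cfg3$expression_noise_sd <- 1
  set.seed(1)
  e3 <- make_expression(cfg3, ths)
  expect_lt(abs(cor(e3[, 1], ths[, "act", 1])), 0.12)
})
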