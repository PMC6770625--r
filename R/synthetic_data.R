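# Fully in-silico inputs for the pipeline: genes on disjoint TSS slots,
# retroelement intervals in three classes, histone-tag BEDs per mark and
# cell line with a controllable RE-linked fraction per gene, pathway / term
# / category gene sets, expression coupled to mark intensities, and truth
# tables (read only by tests, never by the pipeline).
#
# Depth model per gene g, mark m, cell line l:
#   THS ~ NegBin(mean = tags_per_gene_mean * base_g * module_g * tilt_g^s_m,
#                size = tag_dispersion)
# with base_g a per-gene promoter-strength factor (lognormal, shared across
# marks and lines), module_g a pathway co-regulation factor, tilt_g the
# activity tilt with exponent s_m = +1 for active marks and -1 for
# repressive marks (this generates the two anticorrelated mark groups), and
# independent negative-binomial sampling noise per cell line. Each tag is
# then RE-linked with the gene's planted fraction (placed overlapping a
# sampled retroelement inside the TSS window) or background (placed
# uniformly in the window, avoiding retroelements when possible).

#' Build a validated simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 2000 genes, 100 planted RRE-enriched genes with
#' RE-linked tag fraction 0.8 and 100 planted deficient genes at 0.05
#' against a background of 0.2, a mean of 40 tags per gene per mark and
#' cell line, five marks in two anticorrelated groups, and five cell lines.
#'
#' @param seed integer seed; recorded in every output header.
#' @param n_chromosomes,n_genes,halfwidth genome layout; genes occupy
#'   disjoint `gene_spacing`-sized slots so TSS neighborhoods never overlap
#'   and planted truth stays unambiguous.
#' @param gene_spacing bases between consecutive gene slots.
#' @param re_density expected retroelements per 10 kb (before within-class
#'   overlap pruning), split by `re_class_weights`.
#' @param re_class_weights named mixture weights over SINE/LINE/LTR_ERV.
#' @param marks named character vector: mark name -> `"active"` or
#'   `"repressive"`.
#' @param cell_lines cell-line labels.
#' @param tags_per_gene_mean expected THS per gene/mark/line.
#' @param tag_dispersion negative-binomial size; `Inf` gives Poisson counts.
#' @param tag_length tag interval length in bases.
#' @param gene_depth_sdlog sdlog of the per-gene promoter-strength factor.
#' @param mark_tilt_sdlog sdlog of the activity tilt separating the two
#'   mark groups.
#' @param pathway_factor_sdlog sdlog of the pathway co-regulation factor.
#' @param background_re_fraction probability a background gene's tag is
#'   RE-linked.
#' @param planted_enriched,planted_deficient lists `list(count=, fraction=)`;
#'   must bracket the background fraction.
#' @param n_pathways,pathway_size_range,pathway_purity,n_planted_pathways
#'   pathway gene sets; planted pathways draw `pathway_purity` of their
#'   members from the planted enriched genes.
#' @param n_terms,term_size_range,term_purity,n_planted_terms GO-term-like
#'   gene sets for the gene-level enrichment stage.
#' @param category_example_size genes per category example term.
#' @param expression_coupling named vector `c(active=, repressive=)`:
#'   slopes of expression on summed active-mark and repressive-mark THS
#'   (the repressive coupling enters with a negative sign).
#' @param expression_noise_sd noise sd relative to the sd of the noiseless
#'   expression signal.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 4L,
                       n_genes = 2000L,
                       halfwidth = 5000L,
                       gene_spacing = 15000L,
                       re_density = 8,
                       re_class_weights = c(SINE = 0.65, LINE = 0.25,
                                            LTR_ERV = 0.1),
                       marks = c(H3K4me3 = "active", H3K9ac = "active",
                                 H3K27ac = "active", H3K27me3 = "repressive",
                                 H3K9me3 = "repressive"),
                       cell_lines = paste0("CL", 1:5),
                       tags_per_gene_mean = 40,
                       tag_dispersion = 8,
                       tag_length = 100L,
                       gene_depth_sdlog = 0.8,
                       mark_tilt_sdlog = 0.7,
                       pathway_factor_sdlog = 0.6,
                       background_re_fraction = 0.2,
                       planted_enriched = list(count = 100L, fraction = 0.8),
                       planted_deficient = list(count = 100L, fraction = 0.05),
                       n_pathways = 100L,
                       pathway_size_range = c(8L, 20L),
                       pathway_purity = 0.8,
                       n_planted_pathways = 10L,
                       n_terms = 40L,
                       term_size_range = c(15L, 40L),
                       term_purity = 0.8,
                       n_planted_terms = 8L,
                       category_example_size = 60L,
                       expression_coupling = c(active = 1, repressive = 1),
                       expression_noise_sd = 0.3) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("seed is mandatory and must be a single integer", call. = FALSE)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (!(planted_enriched$fraction > background_re_fraction &&
        background_re_fraction > planted_deficient$fraction))
    stop("need planted_enriched$fraction > background_re_fraction > ",
         "planted_deficient$fraction", call. = FALSE)
  counts <- c(cfg$n_chromosomes, cfg$n_genes, cfg$halfwidth,
              cfg$tags_per_gene_mean, cfg$n_pathways, cfg$n_terms)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (planted_enriched$count + planted_deficient$count >= n_genes)
    stop("planted gene counts exceed the universe", call. = FALSE)
  if (!all(marks %in% c("active", "repressive")))
    stop("each mark must be tagged 'active' or 'repressive'", call. = FALSE)
  cfg$chrom_length <- as.integer(
    ceiling(n_genes / n_chromosomes) * gene_spacing + gene_spacing)
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @rdname sim_config_io
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), c(known, "chrom_length"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw$chrom_length <- NULL
  for (nm in c("re_class_weights", "marks", "expression_coupling"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}

#' @param config a `sim_config`.
#' @rdname sim_config_io
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  # yaml drops names on atomic vectors; maps survive the round trip
  for (nm in c("re_class_weights", "marks", "expression_coupling"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

.runif_int <- function(n, lo, hi) {
  # uniform integer in [lo, hi], vectorized over lo/hi
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

.sim_genes <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  chrom <- rep(paste0("chrS", seq_len(cfg$n_chromosomes)),
               each = per_chrom)[seq_len(cfg$n_genes)]
  slot <- (sequence(rle(chrom)$lengths) - 1L) * cfg$gene_spacing
  jitter_max <- max(0L, (cfg$gene_spacing - 2L * cfg$halfwidth) %/% 2L - 1000L)
  tss <- slot + cfg$halfwidth + 1000L +
    .runif_int(cfg$n_genes, 0L, 2L * jitter_max)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - 1999L)
  end <- ifelse(strand == "+", tss + 2000L, tss + 1L)
  data.frame(gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
             symbol = sprintf("SYN%04d", seq_len(cfg$n_genes)),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

.sim_repeats <- function(cfg) {
  fam <- c(SINE = "AluSyn", LINE = "L1Syn", LTR_ERV = "ERVSyn")
  len_rng <- list(SINE = c(150L, 350L), LINE = c(500L, 2500L),
                  LTR_ERV = c(300L, 1200L))
  out <- list()
  for (ch in paste0("chrS", seq_len(cfg$n_chromosomes))) {
    for (cl in names(cfg$re_class_weights)) {
      lambda <- cfg$chrom_length / 1e4 * cfg$re_density *
        cfg$re_class_weights[[cl]]
      n <- stats::rpois(1L, lambda)
      if (n == 0L) next
      start <- sort(.runif_int(n, 0L, cfg$chrom_length - 5000L))
      len <- .runif_int(n, len_rng[[cl]][1], len_rng[[cl]][2])
      end <- start + len
      keep <- rep(TRUE, n)         # drop within-class overlaps, keep first
      if (n > 1L) {
        hi <- end[1]
        for (i in 2:n) {
          if (start[i] < hi) keep[i] <- FALSE else hi <- end[i]
        }
      }
      out[[paste(ch, cl)]] <- data.frame(
        chrom = ch, start = start[keep], end = end[keep],
        strand = sample(c("+", "-"), sum(keep), replace = TRUE),
        name = fam[[cl]], re_class = cl, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

.sim_gene_sets <- function(cfg, genes, planted_enr) {
  ids <- genes$gene_id
  background <- setdiff(ids, planted_enr)
  draw <- function(pool, size) sample(pool, min(size, length(pool)))
  sizes <- .runif_int(cfg$n_pathways, cfg$pathway_size_range[1],
                      cfg$pathway_size_range[2])
  pathways <- vector("list", cfg$n_pathways)
  planted_pw <- seq_len(cfg$n_planted_pathways)
  for (p in seq_len(cfg$n_pathways)) {
    pid <- sprintf("PW%03d", p)
    if (p %in% planted_pw) {
      n_pl <- round(cfg$pathway_purity * sizes[p])
      g <- c(draw(planted_enr, n_pl), draw(background, sizes[p] - n_pl))
    } else g <- draw(background, sizes[p])
    pathways[[p]] <- list(pathway_id = pid, source = "synthetic",
                          description = if (p %in% planted_pw)
                            "planted" else "background",
                          genes = g)
  }
  names(pathways) <- vapply(pathways, `[[`, "", "pathway_id")

  # categories: one planted-module exemplar + three disjoint background pools
  pools <- split(background, rep_len(1:3, length(background)))
  categories <- list(
    planted_module = list(draw(planted_enr, cfg$category_example_size)),
    module_A = list(draw(pools[[1]], cfg$category_example_size)),
    module_B = list(draw(pools[[2]], cfg$category_example_size)),
    module_C = list(draw(pools[[3]], cfg$category_example_size)))

  t_sizes <- .runif_int(cfg$n_terms, cfg$term_size_range[1],
                        cfg$term_size_range[2])
  terms <- vector("list", cfg$n_terms)
  planted_tm <- seq_len(cfg$n_planted_terms)
  for (t in seq_len(cfg$n_terms)) {
    tid <- sprintf("TERM%03d", t)
    if (t %in% planted_tm) {
      n_pl <- round(cfg$term_purity * t_sizes[t])
      g <- c(draw(planted_enr, n_pl), draw(background, t_sizes[t] - n_pl))
    } else {
      pool <- pools[[1L + (t %% 3L)]]
      g <- draw(pool, t_sizes[t])
    }
    terms[[t]] <- list(pathway_id = tid, source = "synthetic",
                       description = if (t %in% planted_tm)
                         "planted" else "background",
                       genes = g)
  }
  names(terms) <- vapply(terms, `[[`, "", "pathway_id")
  list(pathways = pathways, categories = categories, terms = terms,
       planted_pathways = names(pathways)[planted_pw],
       planted_terms = names(terms)[planted_tm])
}

# place tags for one mark x cell-line slice; returns a data.frame of tag
# intervals plus the per-gene intended counts and the fallback count
.place_tags <- function(cfg, nb, re_df, gr_re, re_by_gene, ths, hes) {
  L <- cfg$tag_length
  n_genes <- nrow(nb)
  # RE-linked tags: sample one RE (overlapping the window) per tag
  g_re <- rep.int(seq_len(n_genes), hes)
  no_re <- re_by_gene$n[g_re] == 0L
  n_fallback <- sum(no_re)
  g_bg <- c(rep.int(seq_len(n_genes), ths - hes), g_re[no_re])
  g_re <- g_re[!no_re]
  tag_re <- NULL
  if (length(g_re)) {
    pick <- re_by_gene$offset[g_re] +
      .runif_int(length(g_re), 1L, re_by_gene$n[g_re])
    ridx <- re_by_gene$re_idx[pick]
    lo <- pmax(pmax(re_df$start[ridx], nb$start[g_re]) - L + 1L, 0L)
    hi <- pmin(re_df$end[ridx], nb$end[g_re]) - 1L
    s <- .runif_int(length(g_re), lo, hi)
    tag_re <- data.frame(chrom = nb$chrom[g_re], start = s, end = s + L,
                         stringsAsFactors = FALSE)
  }
  tag_bg <- NULL
  if (length(g_bg)) {
    s <- .runif_int(length(g_bg), nb$start[g_bg], nb$end[g_bg] - L)
    # avoid REs where possible: resample offenders a bounded number of times
    for (round in 1:30) {
      gr_t <- GenomicRanges::GRanges(nb$chrom[g_bg],
                                     IRanges::IRanges(s + 1L, s + L))
      bad <- GenomicRanges::countOverlaps(gr_t, gr_re) > 0L
      if (!any(bad)) break
      s[bad] <- .runif_int(sum(bad), nb$start[g_bg[bad]],
                           nb$end[g_bg[bad]] - L)
    }
    n_fallback <- n_fallback + sum(bad)
    tag_bg <- data.frame(chrom = nb$chrom[g_bg], start = s, end = s + L,
                         stringsAsFactors = FALSE)
  }
  tags <- rbind(tag_re, tag_bg)
  if (is.null(tags))
    tags <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  tags <- tags[order(tags$chrom, tags$start, tags$end), , drop = FALSE]
  list(tags = tags, n_fallback = n_fallback)
}

#' Expression coupled to mark intensities
#'
#' `expr = c_active * sum(active-mark THS) - c_repressive *
#' sum(repressive-mark THS) + noise`, per gene and cell line. Uses the
#' current RNG stream for the noise.
#'
#' @param config a `sim_config`.
#' @param ths 3-d array `gene x mark x cell line` of total hit counts
#'   (dimnames required on mark and cell-line margins).
#' @return numeric matrix `gene x cell line`.
#' @export
make_expression <- function(config, ths) {
  stopifnot(length(dim(ths)) == 3L)
  act <- names(config$marks)[config$marks == "active"]
  rep_ <- names(config$marks)[config$marks == "repressive"]
  out <- sapply(dimnames(ths)[[3]], function(l) {
    a <- if (length(act) == 1L) ths[, act, l] else rowSums(ths[, act, l])
    r <- if (length(rep_) == 1L) ths[, rep_, l] else rowSums(ths[, rep_, l])
    config$expression_coupling[["active"]] * a -
      config$expression_coupling[["repressive"]] * r
  })
  if (config$expression_noise_sd > 0) {
    s <- stats::sd(as.numeric(out))
    if (!is.finite(s) || s == 0) s <- 1
    out <- out + matrix(stats::rnorm(length(out), 0,
                                     config$expression_noise_sd * s),
                        nrow = nrow(out))
  }
  rownames(out) <- dimnames(ths)[[1]]
  out
}

#' Simulate a complete input file set
#'
#' Writes, under `outdir`: `genes.bed`, `repeats.bed`, one
#' `tags_<mark>_<cellline>.bed` per slice, `pathways.gmt`, `terms.gmt`,
#' `categories.gmt`, `expression.tsv`, `truth_genes.tsv`,
#' `truth_sets.tsv` and `config.yaml`. All outputs carry a `# seed=` header
#' (GMT excepted, as the format has no comments) and are byte-identical for
#' identical seed and configuration. Truth files are meant for validation
#' only and are never read by the pipeline stages.
#'
#' @param config a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return (invisibly) a manifest list: file paths, the per-gene truth
#'   table, planted set ids, and the count of RE-linked draws that fell
#'   back to background placement because a window held no retroelement.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  hdr <- paste0("seed=", cfg$seed)

  genes <- .sim_genes(cfg)
  re_df <- .sim_repeats(cfg)
  nb <- tss_neighborhood(genes, cfg$halfwidth)

  status <- rep("background", cfg$n_genes)
  idx_enr <- sample(cfg$n_genes, cfg$planted_enriched$count)
  idx_def <- sample(setdiff(seq_len(cfg$n_genes), idx_enr),
                    cfg$planted_deficient$count)
  status[idx_enr] <- "enriched"
  status[idx_def] <- "deficient"
  frac <- rep(cfg$background_re_fraction, cfg$n_genes)
  frac[idx_enr] <- cfg$planted_enriched$fraction
  frac[idx_def] <- cfg$planted_deficient$fraction

  sets <- .sim_gene_sets(cfg, genes, genes$gene_id[idx_enr])

  # depth factors
  base <- stats::rlnorm(cfg$n_genes, -cfg$gene_depth_sdlog^2 / 2,
                        cfg$gene_depth_sdlog)
  # meanlog 0 so that E[tilt^s] is the same for s = +1 and -1; the shared
  # factor exp(sd^2/2) is divided out of mu below
  tilt <- stats::rlnorm(cfg$n_genes, 0, cfg$mark_tilt_sdlog)
  pfac <- stats::rlnorm(cfg$n_pathways, -cfg$pathway_factor_sdlog^2 / 2,
                        cfg$pathway_factor_sdlog)
  module <- rep(1, cfg$n_genes)
  for (p in rev(seq_along(sets$pathways))) {
    gi <- match(sets$pathways[[p]]$genes, genes$gene_id)
    module[gi] <- pfac[p]
  }

  # per-gene RE index lists (REs overlapping each TSS window)
  gr_nb <- .as_granges(nb)
  gr_re <- .as_granges(re_df)
  ov <- GenomicRanges::findOverlaps(gr_nb, gr_re)
  qh <- S4Vectors::queryHits(ov)
  re_idx <- S4Vectors::subjectHits(ov)[order(qh)]
  n_per_gene <- tabulate(qh, nbins = cfg$n_genes)
  re_by_gene <- list(re_idx = re_idx,
                     n = n_per_gene,
                     offset = cumsum(c(0L, n_per_gene[-cfg$n_genes])))

  marks <- names(cfg$marks)
  ths_arr <- array(0L, dim = c(cfg$n_genes, length(marks),
                               length(cfg$cell_lines)),
                   dimnames = list(genes$gene_id, marks, cfg$cell_lines))
  tag_files <- character()
  n_fallback <- 0L
  for (m in marks) {
    s_m <- if (cfg$marks[[m]] == "active") 1 else -1
    mu <- cfg$tags_per_gene_mean * base * module * tilt^s_m *
      exp(-cfg$mark_tilt_sdlog^2 / 2)
    for (l in cfg$cell_lines) {
      ths <- if (is.finite(cfg$tag_dispersion))
        stats::rnbinom(cfg$n_genes, mu = mu, size = cfg$tag_dispersion)
      else stats::rpois(cfg$n_genes, mu)
      hes <- stats::rbinom(cfg$n_genes, ths, frac)
      ths_arr[, m, l] <- ths
      placed <- .place_tags(cfg, nb, re_df, gr_re, re_by_gene, ths, hes)
      n_fallback <- n_fallback + placed$n_fallback
      f <- file.path(outdir, paste0("tags_", m, "_", l, ".bed"))
      write_bed(placed$tags, f, comment = hdr)
      tag_files <- c(tag_files, f)
    }
  }
  if (n_fallback > 0L)
    message("simulate_dataset: ", n_fallback,
            " RE-linked draw(s) fell back to background placement")

  expr <- make_expression(cfg, ths_arr)
  expr_df <- data.frame(gene_id = genes$gene_id, expr, check.names = FALSE,
                        stringsAsFactors = FALSE)

  paths <- list(
    genes = file.path(outdir, "genes.bed"),
    repeats = file.path(outdir, "repeats.bed"),
    tags = tag_files,
    pathways = file.path(outdir, "pathways.gmt"),
    terms = file.path(outdir, "terms.gmt"),
    categories = file.path(outdir, "categories.gmt"),
    expression = file.path(outdir, "expression.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_sets = file.path(outdir, "truth_sets.tsv"),
    config = file.path(outdir, "config.yaml"))

  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, name = genes$gene_id, score = 0L,
                       strand = genes$strand), paths$genes, comment = hdr)
  write_bed(data.frame(chrom = re_df$chrom, start = re_df$start,
                       end = re_df$end,
                       name = paste0(re_df$name, "|", re_df$re_class),
                       score = 0L, strand = re_df$strand),
            paths$repeats, comment = hdr)
  write_gmt(sets$pathways, paths$pathways)
  write_gmt(sets$terms, paths$terms)
  cat_sets <- lapply(names(sets$categories), function(nm)
    list(pathway_id = nm, description = "category_example",
         genes = sets$categories[[nm]][[1]]))
  write_gmt(cat_sets, paths$categories)
  write_scores_tsv(expr_df, paths$expression, comment = hdr)

  truth_genes <- data.frame(gene_id = genes$gene_id, status = status,
                            re_fraction = frac, stringsAsFactors = FALSE)
  write_scores_tsv(truth_genes, paths$truth_genes, comment = hdr)
  truth_sets <- data.frame(
    set_id = c(names(sets$pathways), names(sets$terms)),
    kind = rep(c("pathway", "term"),
               c(length(sets$pathways), length(sets$terms))),
    planted = c(names(sets$pathways) %in% sets$planted_pathways,
                names(sets$terms) %in% sets$planted_terms),
    stringsAsFactors = FALSE)
  write_scores_tsv(truth_sets, paths$truth_sets, comment = hdr)
  write_sim_config(cfg, paths$config)

  invisible(list(paths = paths, truth_genes = truth_genes,
                 truth_sets = truth_sets,
                 planted_pathways = sets$planted_pathways,
                 planted_terms = sets$planted_terms,
                 n_fallback = n_fallback))
}
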