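# Stage orchestration. Each stage consumes only files and its RunConfig,
# never in-memory state from another stage, so any stage can be re-run in
# isolation; outputs are written to "<file>.partial" and renamed on stage
# success, so a failed stage leaves only .partial files behind.

#' Default run configuration
#'
#' @param seed integer seed (used by the simulate stage and recorded in all
#'   output headers).
#' @param outdir output directory.
#' @param inputs named list of input paths (`genes`, `repeats`, `tags_dir`,
#'   `pathways`, `terms`, `categories`, `expression`); filled automatically
#'   by the simulate stage when running `run-all`.
#' @param ... overrides for top-level keys (`halfwidth`, `outlier`,
#'   `correlation`, `fisher_epsilon`, `marks`, `cell_lines`, `simulate`).
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed, outdir, inputs = list(), ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    halfwidth = 5000L,
    marks = c(H3K4me3 = "active", H3K9ac = "active", H3K27ac = "active",
              H3K27me3 = "repressive", H3K9me3 = "repressive"),
    cell_lines = paste0("CL", 1:5),
    outlier = list(fraction = 0.05, direction = "high_y_enriched"),
    correlation = list(method = "pearson", profile_kind = "gre"),
    fisher_epsilon = 1e-300,
    simulate = list(),
    inputs = inputs)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the keys of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config key missing: seed", call. = FALSE)
  if (is.null(raw$outdir)) stop("config key missing: outdir", call. = FALSE)
  args <- raw[setdiff(names(raw), c("seed", "outdir", "inputs"))]
  for (nm in c("marks", "cell_lines"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  do.call(run_config, c(list(seed = raw$seed, outdir = raw$outdir,
                             inputs = if (is.null(raw$inputs)) list()
                             else raw$inputs),
                        args))
}

.config_hash <- function(cfg) {
  x <- unclass(cfg)
  # hash only the analysis parameters: paths do not affect results
  x$outdir <- NULL
  x$inputs <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

.hdr <- function(cfg) {
  c(paste0("retrospect version=",
           as.character(utils::packageVersion("retrospect"))),
    paste0("seed=", cfg$seed),
    paste0("config_hash=", .config_hash(cfg)))
}

.log <- function(cfg, ...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

.stage_writer <- function() {
  written <- character()
  list(
    write = function(fun, path, ...) {
      fun(..., path = paste0(path, ".partial"))
      written <<- c(written, path)
      path
    },
    commit = function() {
      for (p in written) file.rename(paste0(p, ".partial"), p)
      written
    })
}

.summary_line <- function(cfg, stage, counts) {
  f <- file.path(cfg$outdir, "run_summary.jsonl")
  line <- jsonlite::toJSON(c(list(stage = stage), counts), auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = f, append = TRUE)
}

.require_inputs <- function(cfg, keys) {
  for (k in keys) {
    p <- cfg$inputs[[k]]
    if (is.null(p))
      stop("config key missing: inputs$", k, call. = FALSE)
    if (!all(file.exists(unlist(p))))
      stop("input does not exist (config key inputs$", k, "): ",
           paste(unlist(p)[!file.exists(unlist(p))], collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

.tag_path <- function(cfg, mark, line)
  file.path(cfg$inputs$tags_dir, paste0("tags_", mark, "_", line, ".bed"))

.slices <- function(cfg) {
  expand.grid(mark = names(cfg$marks), cell_line = cfg$cell_lines,
              stringsAsFactors = FALSE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate the synthetic input file set and point
#' `inputs` at it), `count` (per-slice THS/HES tables and RE-class tag
#' fractions), `score` (per-slice and cell-line-averaged gene and pathway
#' scores), `outliers` (RRE-enriched/-deficient calls per mark),
#' `enrich` (gene- and pathway-level category enrichment, combined),
#' `correlate` (profile correlation matrix, dendrogram, expression
#' correlations), or `run-all` chaining all of the above.
#'
#' @param name stage name.
#' @param cfg a `run_config`.
#' @return (invisibly) the possibly updated `run_config` (the simulate
#'   stage fills `inputs`).
#' @export
run_stage <- function(name = c("simulate", "count", "score", "outliers",
                               "enrich", "correlate", "run-all"), cfg) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (name == "run-all") {
    for (st in c("simulate", "count", "score", "outliers", "enrich",
                 "correlate"))
      cfg <- run_stage(st, cfg)
    return(invisible(cfg))
  }
  .log(cfg, "stage ", name, " started")
  t0 <- Sys.time()
  fn <- switch(name, simulate = .stage_simulate, count = .stage_count,
               score = .stage_score, outliers = .stage_outliers,
               enrich = .stage_enrich, correlate = .stage_correlate)
  cfg <- fn(cfg)
  .log(cfg, "stage ", name, " finished in ",
       sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(cfg)
}

.stage_simulate <- function(cfg) {
  simdir <- file.path(cfg$outdir, "sim")
  sc <- do.call(sim_config,
                c(list(seed = cfg$seed,
                       halfwidth = cfg$halfwidth,
                       marks = cfg$marks,
                       cell_lines = cfg$cell_lines),
                  cfg$simulate))
  man <- simulate_dataset(sc, simdir)
  cfg$inputs <- utils::modifyList(cfg$inputs, list(
    genes = man$paths$genes, repeats = man$paths$repeats,
    tags_dir = simdir, pathways = man$paths$pathways,
    terms = man$paths$terms, categories = man$paths$categories,
    expression = man$paths$expression))
  .summary_line(cfg, "simulate",
                list(n_genes = sc$n_genes,
                     n_tag_files = length(man$paths$tags),
                     n_fallback = man$n_fallback))
  invisible(cfg)
}

.stage_count <- function(cfg) {
  .require_inputs(cfg, c("genes", "repeats", "tags_dir"))
  genes <- read_gene_table(cfg$inputs$genes, "bed6")
  repeats <- read_repeat_table(cfg$inputs$repeats, "bed6_class_in_name")
  sl <- .slices(cfg)
  w <- .stage_writer()
  frac_rows <- list()
  for (i in seq_len(nrow(sl))) {
    m <- sl$mark[i]; l <- sl$cell_line[i]
    tp <- .tag_path(cfg, m, l)
    if (!file.exists(tp))
      stop("input does not exist (config key inputs$tags_dir): ", tp,
           call. = FALSE)
    tags <- read_tag_bed(tp, m, l)
    counts <- gene_hit_counts(genes, tags, repeats, cfg$halfwidth,
                              mark = m, cell_line = l)
    w$write(write_scores_tsv, file.path(cfg$outdir,
                                        paste0("counts_", m, "_", l, ".tsv")),
            records = counts, comment = .hdr(cfg))
    fr <- class_fractions(tags, repeats)
    frac_rows[[i]] <- data.frame(
      mark = m, cell_line = l, total_tags = fr$total_tags,
      fraction_re_linked = fr$fraction_re_linked,
      as.list(stats::setNames(fr$per_class,
                              paste0("fraction_", names(fr$per_class)))),
      stringsAsFactors = FALSE)
  }
  w$write(write_scores_tsv, file.path(cfg$outdir, "class_fractions.tsv"),
          records = do.call(rbind, frac_rows), comment = .hdr(cfg))
  w$commit()
  .summary_line(cfg, "count", list(n_slices = nrow(sl),
                                   n_genes = nrow(genes)))
  invisible(cfg)
}

.stage_score <- function(cfg) {
  .require_inputs(cfg, "pathways")
  pathways <- read_gmt(cfg$inputs$pathways)
  sl <- .slices(cfg)
  w <- .stage_writer()
  n_slices <- 0L
  for (m in unique(sl$mark)) {
    gtabs <- list(); ptabs <- list()
    for (l in cfg$cell_lines) {
      cf <- file.path(cfg$outdir, paste0("counts_", m, "_", l, ".tsv"))
      if (!file.exists(cf))
        stop("missing counts table (run the count stage first): ", cf,
             call. = FALSE)
      counts <- read_scores_tsv(cf)
      gs <- gene_score_table(counts)
      gtabs[[l]] <- gs
      ptabs[[l]] <- compute_pathway_scores(
        pathways, stats::setNames(gs$gre, gs$gene_id),
        stats::setNames(gs$ghe, gs$gene_id), mark = m, cell_line = l)
      w$write(write_scores_tsv,
              file.path(cfg$outdir, paste0("scores_genes_", m, "_", l, ".tsv")),
              records = gs, comment = .hdr(cfg))
      w$write(write_scores_tsv,
              file.path(cfg$outdir,
                        paste0("scores_pathways_", m, "_", l, ".tsv")),
              records = ptabs[[l]], comment = .hdr(cfg))
      n_slices <- n_slices + 1L
    }
    gavg <- average_across_cell_lines(gtabs,
                                      stats_cols = c("gre", "ghe", "ngre"))
    gavg$mark <- m
    pavg <- average_across_cell_lines(ptabs,
                                      stats_cols = c("pii", "pgi", "npii"))
    pavg$mark <- m
    w$write(write_scores_tsv,
            file.path(cfg$outdir, paste0("scores_genes_", m, "_averaged.tsv")),
            records = gavg, comment = .hdr(cfg))
    w$write(write_scores_tsv,
            file.path(cfg$outdir,
                      paste0("scores_pathways_", m, "_averaged.tsv")),
            records = pavg, comment = .hdr(cfg))
  }
  w$commit()
  .summary_line(cfg, "score", list(n_slices = n_slices,
                                   n_pathways = length(pathways)))
  invisible(cfg)
}

.call_items <- function(tab, id_col, x_col, y_col) {
  data.frame(item_id = tab[[id_col]], x = tab[[x_col]], y = tab[[y_col]],
             stringsAsFactors = FALSE)
}

.stage_outliers <- function(cfg) {
  w <- .stage_writer()
  n_called <- 0L
  dir_map <- if (identical(cfg$outlier$direction, "as_printed"))
    "as_printed" else "high_y_enriched"
  for (m in names(cfg$marks)) {
    for (level in c("genes", "pathways")) {
      f <- file.path(cfg$outdir,
                     paste0("scores_", level, "_", m, "_averaged.tsv"))
      if (!file.exists(f))
        stop("missing averaged score table (run the score stage first): ", f,
             call. = FALSE)
      tab <- read_scores_tsv(f)
      items <- if (level == "genes")
        .call_items(tab, "gene_id", "gre", "ngre")
      else .call_items(tab, "pathway_id", "pii", "npii")
      calls <- select_outliers(items, fraction = cfg$outlier$fraction,
                               direction = dir_map)
      out <- as.data.frame(calls)
      out$slope <- attr(calls, "model")$slope
      w$write(write_scores_tsv,
              file.path(cfg$outdir, paste0("calls_", level, "_", m, ".tsv")),
              records = out, comment = .hdr(cfg))
      n_called <- n_called + attr(calls, "k") * 2L
    }
  }
  w$commit()
  .summary_line(cfg, "outliers", list(n_calls = n_called))
  invisible(cfg)
}

.stage_enrich <- function(cfg) {
  .require_inputs(cfg, c("terms", "categories", "pathways"))
  terms <- read_gmt(cfg$inputs$terms)
  pathways <- read_gmt(cfg$inputs$pathways)
  cat_sets <- read_gmt(cfg$inputs$categories)
  categories <- lapply(cat_sets, function(s) list(s$genes))
  names(categories) <- names(cat_sets)
  pw_cat <- vapply(pathways, function(p)
    assign_to_category(p$genes, categories), "")
  w <- .stage_writer()
  for (m in names(cfg$marks)) {
    gcalls <- .read_calls(cfg, "genes", m)
    pcalls <- .read_calls(cfg, "pathways", m)
    universe <- gcalls$item_id
    gt <- gene_level_category_table(gcalls, terms, universe, categories)
    pt <- pathway_level_category_table(pcalls, pw_cat)
    comb <- combine_gene_pathway(gt, pt)
    comb$mark <- m
    w$write(write_scores_tsv,
            file.path(cfg$outdir, paste0("enrichment_", m, ".tsv")),
            records = comb, comment = .hdr(cfg))
  }
  w$write(write_scores_tsv,
          file.path(cfg$outdir, "pathway_categories.tsv"),
          records = data.frame(pathway_id = names(pw_cat),
                               category = unname(pw_cat),
                               stringsAsFactors = FALSE),
          comment = .hdr(cfg))
  w$commit()
  .summary_line(cfg, "enrich", list(n_terms = length(terms),
                                    n_categories = length(categories)))
  invisible(cfg)
}

.read_calls <- function(cfg, level, m) {
  f <- file.path(cfg$outdir, paste0("calls_", level, "_", m, ".tsv"))
  if (!file.exists(f))
    stop("missing call table (run the outliers stage first): ", f,
         call. = FALSE)
  read_scores_tsv(f)
}

.stage_correlate <- function(cfg) {
  kind <- cfg$correlation$profile_kind
  method <- cfg$correlation$method
  sl <- .slices(cfg)
  tabs <- list()
  for (i in seq_len(nrow(sl))) {
    m <- sl$mark[i]; l <- sl$cell_line[i]
    f <- file.path(cfg$outdir, paste0("scores_genes_", m, "_", l, ".tsv"))
    if (!file.exists(f))
      stop("missing score table (run the score stage first): ", f,
           call. = FALSE)
    tabs[[paste0(m, ".", l)]] <- read_scores_tsv(f)
  }
  prof <- build_profiles(tabs, kind = kind)
  cmat <- correlate_profiles(prof, method = method)
  bc <- bicluster(cmat)
  w <- .stage_writer()
  cdf <- data.frame(label = rownames(cmat), as.data.frame(cmat),
                    check.names = FALSE, stringsAsFactors = FALSE)
  w$write(write_scores_tsv, file.path(cfg$outdir, "profile_correlation.tsv"),
          records = cdf, comment = .hdr(cfg))
  w$write(function(x, path) writeLines(x, path),
          file.path(cfg$outdir, "profile_dendrogram.nwk"), x = bc$newick)

  expr_rows <- NULL
  if (!is.null(cfg$inputs$expression) &&
      file.exists(cfg$inputs$expression %||% "")) {
    expr <- read_scores_tsv(cfg$inputs$expression)
    lines_avail <- intersect(cfg$cell_lines, names(expr))
    if (length(lines_avail)) {
      ids <- tabs[[1]]$gene_id
      expr <- expr[match(ids, expr$gene_id), , drop = FALSE]
      expr_avg <- rowMeans(as.matrix(expr[, lines_avail, drop = FALSE]),
                           na.rm = TRUE)
      expr_rows <- do.call(rbind, lapply(names(cfg$marks), function(m) {
        cols <- paste0(m, ".", cfg$cell_lines)
        sp <- rowMeans(prof[, intersect(cols, colnames(prof)), drop = FALSE],
                       na.rm = TRUE)
        ec <- expression_correlation(sp, expr_avg, method = method,
                                     mark_group = unname(cfg$marks[[m]]))
        data.frame(mark = m, mark_group = ec$mark_group,
                   correlation = ec$correlation, sign = ec$sign,
                   n_complete = ec$n_complete, stringsAsFactors = FALSE)
      }))
      w$write(write_scores_tsv,
              file.path(cfg$outdir, "expression_correlation.tsv"),
              records = expr_rows, comment = .hdr(cfg))
    }
  }
  w$commit()
  .summary_line(cfg, "correlate",
                list(n_profiles = ncol(prof),
                     n_expression_rows = if (is.null(expr_rows)) 0L
                     else nrow(expr_rows)))
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
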