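# Per-gene and per-pathway enrichment scores.
#
# GRE_g  = HES_g / mean(HES) over the gene universe
# GHE_g  = THS_g / mean(THS) over the gene universe
# NGRE_g = GRE_g / GHE_g  (missing when GHE_g = 0)
# PII_p  = mean of member-gene GRE;  PGI_p = mean of member-gene GHE;
# NPII_p = PII_p / PGI_p (missing when PGI_p = 0)

.mean_normalize <- function(x, what) {
  if (!length(x)) stop("empty gene universe", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and non-negative", call. = FALSE)
  m <- mean(x)
  if (m == 0)
    stop("all ", what, " are zero: normalizer undefined", call. = FALSE)
  x / m
}

#' Gene RE-linked enrichment score (GRE)
#'
#' Each gene's RE-linked hit count divided by the mean RE-linked hit count
#' over the whole gene universe, so the returned scores average to 1.
#'
#' @param hes_by_gene named non-negative numeric vector of RE-linked hit
#'   counts over the universe.
#' @return named numeric vector of GRE scores; `mean(gre) == 1`.
#' @export
compute_gre <- function(hes_by_gene) .mean_normalize(hes_by_gene, "HES")

#' Gene hits enrichment score (GHE)
#'
#' Same normalization as [compute_gre()] applied to total hit counts; GHE
#' captures the gene-specific total-coverage trend against which GRE is
#' balanced.
#'
#' @param ths_by_gene named non-negative numeric vector of total hit counts.
#' @return named numeric vector of GHE scores; `mean(ghe) == 1`.
#' @export
compute_ghe <- function(ths_by_gene) .mean_normalize(ths_by_gene, "THS")

#' Normalized gene RE-linked enrichment score (NGRE)
#'
#' `NGRE = GRE / GHE`. Where `GHE = 0` (a gene with no tags at all, hence
#' necessarily `GRE = 0`) the score is missing (`NA`), not 0: a
#' zero-coverage gene carries no evidence and is kept out of outlier calling.
#'
#' @param gre,ghe score vectors over the same universe (same names, same
#'   order).
#' @return named numeric vector; `ngre * ghe == gre` wherever defined.
#' @export
compute_ngre <- function(gre, ghe) {
  if (length(gre) != length(ghe) ||
      (!is.null(names(gre)) && !identical(names(gre), names(ghe))))
    stop("gre and ghe must be over the same gene universe", call. = FALSE)
  ifelse(ghe > 0, gre / ghe, NA_real_)
}

#' Per-gene score table for one mark/cell-line slice
#'
#' @param counts data.frame from [gene_hit_counts()].
#' @return data.frame with `gene_id`, `mark`, `cell_line`, `hes`, `ths`,
#'   `gre`, `ghe`, `ngre`.
#' @export
gene_score_table <- function(counts) {
  gre <- compute_gre(stats::setNames(counts$hes, counts$gene_id))
  ghe <- compute_ghe(stats::setNames(counts$ths, counts$gene_id))
  data.frame(gene_id = counts$gene_id, mark = counts$mark,
             cell_line = counts$cell_line,
             hes = counts$hes, ths = counts$ths,
             gre = as.numeric(gre), ghe = as.numeric(ghe),
             ngre = as.numeric(compute_ngre(gre, ghe)),
             stringsAsFactors = FALSE)
}

#' Pathway involvement scores (PII, PGI, NPII)
#'
#' `PII` is the mean GRE of the pathway's member genes present in the
#' universe, `PGI` the mean GHE of the same members, and `NPII = PII / PGI`.
#' Members absent from the universe are skipped; `n_scored_genes` records
#' how many were used. A pathway with no scored members yields a missing
#' record with a warning.
#'
#' @param pathways list of gene-set definitions as from [read_gmt()].
#' @param gre,ghe named score vectors over the gene universe.
#' @param mark,cell_line labels stored on every row.
#' @return data.frame with `pathway_id`, `mark`, `cell_line`, `pii`, `pgi`,
#'   `npii`, `n_scored_genes`.
#' @export
compute_pathway_scores <- function(pathways, gre, ghe,
                                   mark = NA_character_,
                                   cell_line = NA_character_) {
  stopifnot(length(gre) == length(ghe))
  universe <- names(gre)
  rows <- lapply(pathways, function(p) {
    members <- intersect(p$genes, universe)
    n <- length(members)
    if (n == 0L) {
      warning("pathway '", p$pathway_id,
              "' has no genes in the universe; scores missing", call. = FALSE)
      return(data.frame(pathway_id = p$pathway_id, mark = mark,
                        cell_line = cell_line, pii = NA_real_, pgi = NA_real_,
                        npii = NA_real_, n_scored_genes = 0L,
                        stringsAsFactors = FALSE))
    }
    pii <- mean(gre[members])
    pgi <- mean(ghe[members])
    data.frame(pathway_id = p$pathway_id, mark = mark, cell_line = cell_line,
               pii = pii, pgi = pgi,
               npii = if (pgi > 0) pii / pgi else NA_real_,
               n_scored_genes = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Average score tables across cell lines
#'
#' Takes one score table per cell line (identical item universes) and
#' returns the per-item arithmetic mean of each statistic across lines.
#' Missing values are excluded from each mean and `n_lines_<stat>` records
#' how many lines contributed. Averaging operates on the final per-line
#' statistics, never on pooled counts.
#'
#' @param slices list of data.frames sharing an id column (`gene_id` or
#'   `pathway_id`) and a common set of numeric statistic columns.
#' @param stats_cols statistic columns to average; defaults to all shared
#'   numeric columns except counts of scored genes.
#' @param min_lines minimum number of non-missing lines for the averaged
#'   value to be defined (default 1).
#' @return data.frame with the id column, `cell_line = "averaged"`, the
#'   averaged statistics and per-statistic contributing-line counts.
#' @export
average_across_cell_lines <- function(slices, stats_cols = NULL,
                                      min_lines = 1L) {
  if (!length(slices)) stop("no slices to average", call. = FALSE)
  id_col <- if ("gene_id" %in% names(slices[[1]])) "gene_id" else "pathway_id"
  ids <- slices[[1]][[id_col]]
  for (s in slices)
    if (!identical(s[[id_col]], ids))
      stop("slices do not share an identical universe", call. = FALSE)
  if (is.null(stats_cols)) {
    num <- names(slices[[1]])[vapply(slices[[1]], is.numeric, TRUE)]
    stats_cols <- setdiff(num, c("n_scored_genes"))
  }
  out <- data.frame(id = ids, cell_line = "averaged",
                    stringsAsFactors = FALSE)
  names(out)[1] <- id_col
  for (sc in stats_cols) {
    m <- sapply(slices, function(s) as.numeric(s[[sc]]))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    k <- rowSums(!is.na(m))
    avg <- rowMeans(m, na.rm = TRUE)
    avg[k < min_lines | k == 0L] <- NA_real_
    out[[sc]] <- avg
    out[[paste0("n_lines_", sc)]] <- as.integer(k)
  }
  out
}
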