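# Overlap counting in TSS neighborhoods.
#
# Internally intervals are 0-based half-open; GenomicRanges is 1-based
# closed, so [start, end) maps to IRanges(start + 1, end). Overlap means at
# least one shared base.

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' TSS neighborhood of a gene
#'
#' The window spans `halfwidth` bases upstream and downstream of the TSS
#' (default 5000, i.e. a 10 kb window), irrespective of strand, clipped at
#' position 0. Chromosome ends are not clipped (lengths are unknown to the
#' tool).
#'
#' @param genes gene table from [read_gene_table()] (or any data.frame with
#'   `chrom` and `tss`).
#' @param halfwidth bases on each side of the TSS; must be positive.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open), one
#'   row per gene, plus `gene_id` when present.
#' @export
tss_neighborhood <- function(genes, halfwidth = 5000L) {
  if (!is.numeric(halfwidth) || length(halfwidth) != 1L || halfwidth <= 0)
    stop("halfwidth must be a single positive number", call. = FALSE)
  out <- data.frame(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$tss - halfwidth)),
    end = as.integer(genes$tss + halfwidth),
    stringsAsFactors = FALSE)
  if ("gene_id" %in% names(genes)) out$gene_id <- genes$gene_id
  out
}

#' Total hit count (THS) per gene
#'
#' A tag counts for a gene iff it overlaps the gene's TSS neighborhood by at
#' least one base; a tag may count for several genes, but at most once per
#' gene.
#'
#' @param genes gene table with `gene_id`, `chrom`, `tss`.
#' @param tags tag table with `chrom`, `start`, `end`.
#' @param halfwidth neighborhood halfwidth in bases.
#' @return named integer vector, one THS per `gene_id`.
#' @export
count_total_hits <- function(genes, tags, halfwidth = 5000L) {
  nb <- tss_neighborhood(genes, halfwidth)
  if (nrow(tags) == 0L)
    return(stats::setNames(integer(nrow(nb)), genes$gene_id))
  hits <- GenomicRanges::countOverlaps(.as_granges(nb), .as_granges(tags))
  stats::setNames(as.integer(hits), genes$gene_id)
}

#' RE-linked hit count (HES) per gene
#'
#' A tag is RE-linked for gene g iff (i) it overlaps g's TSS neighborhood
#' and (ii) it overlaps at least one retroelement that itself overlaps the
#' neighborhood. A tag touching several REs still counts once. Tag-RE
#' overlap is evaluated over the full extents of both intervals, not clipped
#' to the window.
#'
#' @inheritParams count_total_hits
#' @param repeats retroelement table with `chrom`, `start`, `end`.
#' @return named integer vector, one HES per `gene_id`.
#' @export
count_re_linked_hits <- function(genes, tags, repeats, halfwidth = 5000L) {
  nb <- tss_neighborhood(genes, halfwidth)
  hes <- stats::setNames(integer(nrow(nb)), genes$gene_id)
  if (nrow(tags) == 0L || nrow(repeats) == 0L) return(hes)
  gr_nb <- .as_granges(nb)
  gr_tag <- .as_granges(tags)
  gr_re <- .as_granges(repeats)
  gt <- GenomicRanges::findOverlaps(gr_nb, gr_tag)   # (gene, tag)
  gr <- GenomicRanges::findOverlaps(gr_nb, gr_re)    # (gene, re)
  tr <- GenomicRanges::findOverlaps(gr_tag, gr_re)   # (tag, re)
  if (!length(gt) || !length(gr) || !length(tr)) return(hes)
  dt_gt <- data.table::data.table(gene = S4Vectors::queryHits(gt),
                                  tag = S4Vectors::subjectHits(gt))
  dt_gr <- data.table::data.table(gene = S4Vectors::queryHits(gr),
                                  re = S4Vectors::subjectHits(gr))
  dt_tr <- data.table::data.table(tag = S4Vectors::queryHits(tr),
                                  re = S4Vectors::subjectHits(tr))
  # (gene, tag) pairs where the tag touches an RE that touches the window
  gtr <- merge(dt_gt, dt_tr, by = "tag", allow.cartesian = TRUE)
  linked <- merge(gtr, dt_gr, by = c("gene", "re"))
  if (!nrow(linked)) return(hes)
  cnt <- unique(linked[, c("gene", "tag")])[, .N, by = "gene"]
  hes[cnt$gene] <- cnt$N
  hes
}

#' Per-gene hit-count table for one mark and cell line
#'
#' @inheritParams count_re_linked_hits
#' @param mark,cell_line labels stored on every row.
#' @return data.frame with `gene_id`, `mark`, `cell_line`, `ths`, `hes`;
#'   `hes <= ths` always holds.
#' @export
gene_hit_counts <- function(genes, tags, repeats, halfwidth = 5000L,
                            mark = unique(tags$mark),
                            cell_line = unique(tags$cell_line)) {
  ths <- count_total_hits(genes, tags, halfwidth)
  hes <- count_re_linked_hits(genes, tags, repeats, halfwidth)
  stopifnot(all(hes <= ths))
  data.frame(gene_id = genes$gene_id,
             mark = if (length(mark)) mark[1] else NA_character_,
             cell_line = if (length(cell_line)) cell_line[1] else NA_character_,
             ths = as.integer(ths), hes = as.integer(hes),
             stringsAsFactors = FALSE)
}

#' RE-class fractions of a tag set
#'
#' Fraction of tags overlapping any retroelement, and per class the fraction
#' overlapping any RE of that class. A tag overlapping a SINE and a LINE
#' increments both class fractions but the overall fraction once, so the
#' class fractions need not sum to the overall fraction.
#'
#' @param tags tag table.
#' @param repeats retroelement table with `re_class`.
#' @return list with `mark`, `cell_line`, `total_tags`,
#'   `fraction_re_linked`, `per_class` (named numeric over the RE classes
#'   present), and `defined` (FALSE when there are no tags).
#' @export
class_fractions <- function(tags, repeats) {
  mk <- if ("mark" %in% names(tags) && nrow(tags)) tags$mark[1] else NA_character_
  cl <- if ("cell_line" %in% names(tags) && nrow(tags)) tags$cell_line[1] else NA_character_
  n <- nrow(tags)
  if (n == 0L)
    return(list(mark = mk, cell_line = cl, total_tags = 0L,
                fraction_re_linked = NA_real_, per_class = numeric(),
                defined = FALSE))
  gr_tag <- .as_granges(tags)
  any_re <- if (nrow(repeats))
    GenomicRanges::countOverlaps(gr_tag, .as_granges(repeats)) > 0L
  else rep(FALSE, n)
  classes <- sort(unique(repeats$re_class))
  per_class <- vapply(classes, function(cc) {
    sub <- repeats[repeats$re_class == cc, , drop = FALSE]
    mean(GenomicRanges::countOverlaps(gr_tag, .as_granges(sub)) > 0L)
  }, 0)
  list(mark = mk, cell_line = cl, total_tags = n,
       fraction_re_linked = mean(any_re),
       per_class = per_class, defined = TRUE)
}
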