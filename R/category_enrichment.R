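# Functional-category enrichment: category assignment by maximal gene-set
# intersection with example terms, EASE p-values (conservative one-tailed
# hypergeometric with the observed count decremented by one), Fisher's-method
# aggregation across terms, and combination of gene- and pathway-level
# p-values.
#
# No multiple-testing correction is applied anywhere: categories share genes
# and are not independent, so the p-values are usable for ranking only.
# Every output table carries a `ranking_only` flag.

#' Assign a gene set to a functional category
#'
#' The category whose example term shares the most genes with the item wins;
#' ties are broken by the lexicographically smallest category name; a zero
#' intersection with every example term yields `"unassigned"`.
#'
#' @param item_genes non-empty character vector of gene ids.
#' @param categories named list: category name -> list of example terms,
#'   each a character vector of gene ids (a single character vector is also
#'   accepted as a one-example category).
#' @return a single category name, or `"unassigned"`.
#' @export
assign_to_category <- function(item_genes, categories) {
  if (!length(item_genes)) stop("empty item gene set", call. = FALSE)
  if (!length(categories)) stop("no categories supplied", call. = FALSE)
  best <- vapply(categories, function(ex) {
    if (!is.list(ex)) ex <- list(ex)
    max(vapply(ex, function(g) length(intersect(item_genes, g)), 0L))
  }, 0L)
  if (max(best) == 0L) return("unassigned")
  winners <- names(best)[best == max(best)]
  sort(winners)[1]
}

#' EASE enrichment p-value
#'
#' One-sided upper-tail hypergeometric probability of observing at least
#' `max(0, x - 1)` category items when drawing `y` items from a universe of
#' `k` containing `z` category items. Decrementing the observed count by one
#' makes the score conservative relative to the plain Fisher exact upper
#' tail (a single-item overlap is never significant).
#'
#' @param x enriched/deficient items in the category.
#' @param y all enriched/deficient items.
#' @param z all items in the category.
#' @param k all items analyzed.
#' @return p-value in (0, 1].
#' @export
ease_p <- function(x, y, z, k) {
  stopifnot(length(x) == 1L, length(y) == 1L, length(z) == 1L,
            length(k) == 1L)
  if (any(c(x, y, z, k) < 0) || x > min(y, z) || y > k || z > k)
    stop("invalid contingency counts: need 0 <= x <= min(y, z), y <= k, z <= k",
         call. = FALSE)
  x_adj <- max(0, x - 1)
  # P(W >= x_adj), W ~ Hypergeometric(k, z, y)
  stats::phyper(x_adj - 1, m = z, n = k - z, k = y, lower.tail = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to the upper tail of a chi-square
#' distribution with `2 * length(p)` degrees of freedom. Values below
#' `epsilon` are clipped with a warning to keep the statistic finite.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param epsilon smallest allowed p (default 1e-300).
#' @return aggregated p-value.
#' @export
fisher_combine <- function(p_values, epsilon = 1e-300) {
  if (!length(p_values)) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must be in (0, 1]", call. = FALSE)
  if (any(p_values < epsilon)) {
    warning("p-value(s) below epsilon clipped to ", epsilon, call. = FALSE)
    p_values <- pmax(p_values, epsilon)
  }
  x2 <- -2 * sum(log(p_values))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

.call_sets <- function(calls) {
  list(up = calls$item_id[calls$label == "RRE_enriched"],
       down = calls$item_id[calls$label == "RRE_deficient"])
}

#' Gene-level category enrichment table
#'
#' For each term and each call side (up = RRE-enriched, down =
#' RRE-deficient), builds the contingency counts
#' `x = |term genes in call set|`, `y = |call set|`,
#' `z = |term genes in universe|`, `k = |universe|`, computes the EASE
#' p-value, assigns the term to a category by maximal intersection with the
#' example terms, and aggregates the member-term p-values per category and
#' side with Fisher's method. The background is always the entire analyzed
#' gene universe. Terms with no universe genes are skipped with a warning;
#' categories with no assigned terms are omitted.
#'
#' @param calls an `rre_calls` object on genes (from [select_outliers()]).
#' @param terms list of gene sets (as from [read_gmt()]).
#' @param universe character vector: all analyzed gene ids.
#' @param categories category example terms, see [assign_to_category()].
#' @param overrides optional named character vector `term_id -> category`
#'   replacing the automatic assignment for those terms.
#' @return data.frame with `category`, `direction` (`up`/`down`), `p_gene`,
#'   `n_terms`, `ranking_only = TRUE`.
#' @export
gene_level_category_table <- function(calls, terms, universe, categories,
                                      overrides = NULL) {
  sets <- .call_sets(calls)
  rows <- list()
  term_p <- list(up = list(), down = list())
  for (tm in terms) {
    tg <- intersect(tm$genes, universe)
    if (!length(tg)) {
      warning("term '", tm$pathway_id, "' has no genes in the universe; skipped",
              call. = FALSE)
      next
    }
    cat_name <- if (!is.null(overrides) && tm$pathway_id %in% names(overrides))
      unname(overrides[tm$pathway_id]) else assign_to_category(tg, categories)
    for (side in c("up", "down")) {
      cs <- sets[[side]]
      p <- ease_p(x = length(intersect(tg, cs)), y = length(cs),
                  z = length(tg), k = length(universe))
      term_p[[side]][[cat_name]] <- c(term_p[[side]][[cat_name]], p)
    }
  }
  for (side in c("up", "down"))
    for (cat_name in names(term_p[[side]])) {
      ps <- term_p[[side]][[cat_name]]
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_name, direction = side,
        p_gene = fisher_combine(ps), n_terms = length(ps),
        ranking_only = TRUE, stringsAsFactors = FALSE)
    }
  if (!length(rows))
    return(data.frame(category = character(), direction = character(),
                      p_gene = numeric(), n_terms = integer(),
                      ranking_only = logical(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pathway-level category enrichment table
#'
#' Every pathway must be pre-assigned to exactly one category (via
#' [assign_to_category()] or an override table). Per category and call side
#' the EASE p-value is computed on
#' `x = enriched/deficient pathways in the category`,
#' `y = all enriched/deficient pathways`, `z = pathways in the category`,
#' `k = all pathways`.
#'
#' @param calls an `rre_calls` object on pathways.
#' @param pathway_categories named character vector `pathway_id -> category`
#'   for all analyzed pathways.
#' @return data.frame with `category`, `direction`, `p_pathway`,
#'   `x`, `y`, `z`, `k`, `ranking_only = TRUE`.
#' @export
pathway_level_category_table <- function(calls, pathway_categories) {
  sets <- .call_sets(calls)
  k <- length(pathway_categories)
  cats <- sort(unique(unname(pathway_categories)))
  rows <- list()
  for (cat_name in cats) {
    members <- names(pathway_categories)[pathway_categories == cat_name]
    for (side in c("up", "down")) {
      cs <- sets[[side]]
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_name, direction = side,
        p_pathway = ease_p(x = length(intersect(members, cs)),
                           y = length(cs), z = length(members), k = k),
        x = length(intersect(members, cs)), y = length(cs),
        z = length(members), k = k,
        ranking_only = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Combine gene- and pathway-level category p-values
#'
#' Fisher's-method combination of the two per-category p-values, joined on
#' category and direction. A missing partner propagates to a missing
#' combined value. The result is for qualitative ranking only.
#'
#' @param gene_table output of [gene_level_category_table()].
#' @param pathway_table output of [pathway_level_category_table()].
#' @return data.frame with `category`, `direction`, `p_gene`, `p_pathway`,
#'   `p_combined`, `ranking_only = TRUE`.
#' @export
combine_gene_pathway <- function(gene_table, pathway_table) {
  merged <- merge(gene_table[, c("category", "direction", "p_gene")],
                  pathway_table[, c("category", "direction", "p_pathway")],
                  by = c("category", "direction"), all = TRUE)
  merged$p_combined <- mapply(function(pg, pp) {
    if (is.na(pg) || is.na(pp)) NA_real_ else fisher_combine(c(pg, pp))
  }, merged$p_gene, merged$p_pathway)
  merged$ranking_only <- TRUE
  merged[order(merged$category, merged$direction), , drop = FALSE]
}
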