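# Pairwise correlation of per-gene score profiles (one profile per
# mark x cell line, or averaged), hierarchical biclustering of the
# correlation matrix, and correlation of score profiles with expression.

#' Pairwise correlation matrix of score profiles
#'
#' Profiles are per-gene numeric vectors over a common universe; missing
#' genes are dropped pairwise. An entry is missing (with a warning) when a
#' pair has fewer than 3 complete genes or when either profile is constant
#' over the complete pairs (zero variance). The diagonal is exactly 1
#' wherever defined.
#'
#' @param profiles numeric matrix (genes x profiles, column names are the
#'   profile labels) or a named list of equal-length numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlate_profiles <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    stopifnot(length(unique(lengths(profiles))) == 1L)
    profiles <- do.call(cbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  cc <- suppressWarnings(
    stats::cor(profiles, use = "pairwise.complete.obs", method = method))
  # blank out pairs with fewer than 3 complete observations
  obs <- crossprod(!is.na(profiles))
  few <- obs < 3L
  if (any(few & upper.tri(few, diag = TRUE)))
    warning("correlation undefined for pair(s) with fewer than 3 complete genes",
            call. = FALSE)
  cc[few] <- NA_real_
  diag(cc)[!is.na(diag(cc))] <- 1
  zero_var <- is.na(cc) & !few
  if (any(zero_var[upper.tri(zero_var)]))
    warning("correlation undefined for constant (zero-variance) profile(s)",
            call. = FALSE)
  cc
}

#' Bicluster a correlation matrix
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' distance `d = 1 - c`. Labels are sorted before clustering so the merge
#' order (and hence tie-breaking) is deterministic and independent of the
#' input column order.
#'
#' @param cmat symmetric correlation matrix with no missing entries.
#' @return list with `order` (leaf labels in dendrogram order), `hclust`
#'   (the merge tree) and `newick` (dendrogram as a newick string).
#' @export
bicluster <- function(cmat) {
  if (anyNA(cmat))
    stop("correlation matrix has missing entries; filter the offending ",
         "profile pairs first", call. = FALSE)
  if (is.null(colnames(cmat)))
    colnames(cmat) <- rownames(cmat) <- paste0("P", seq_len(ncol(cmat)))
  ord <- order(colnames(cmat))
  cmat <- cmat[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - cmat)
  hc <- stats::hclust(d, method = "average")
  nw <- ape::write.tree(ape::as.phylo(hc))
  list(order = colnames(cmat)[hc$order], hclust = hc, newick = nw)
}

#' Correlation of a score profile with an expression profile
#'
#' Single pairwise-complete correlation over the shared universe, annotated
#' with the mark group (active / repressive) when supplied.
#'
#' @param score_profile,expression_profile equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param mark_group optional annotation, e.g. `"active"` or `"repressive"`.
#' @return list with `correlation`, `sign`, `n_complete`, `mark_group`.
#' @export
expression_correlation <- function(score_profile, expression_profile,
                                   method = c("pearson", "spearman"),
                                   mark_group = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(score_profile) == length(expression_profile))
  ok <- is.finite(score_profile) & is.finite(expression_profile)
  n <- sum(ok)
  cc <- if (n >= 3L)
    suppressWarnings(stats::cor(score_profile[ok], expression_profile[ok],
                                method = method))
  else NA_real_
  if (is.na(cc))
    warning("expression correlation undefined (constant profile or < 3 ",
            "complete genes)", call. = FALSE)
  list(correlation = cc,
       sign = if (is.na(cc)) NA_character_ else if (cc >= 0) "positive" else "negative",
       n_complete = n, mark_group = mark_group)
}

#' Build score profiles from per-slice score tables
#'
#' @param score_tables named list of per-slice score data.frames (e.g.
#'   `"H3K4me3.CL1"`), each with `gene_id` and the chosen score column.
#' @param kind which per-gene quantity forms the profile: `"gre"`,
#'   `"ngre"` or `"ths"`.
#' @return numeric matrix genes x profiles.
#' @export
build_profiles <- function(score_tables, kind = c("gre", "ngre", "ths")) {
  kind <- match.arg(kind)
  stopifnot(length(score_tables) >= 1L)
  ids <- score_tables[[1]]$gene_id
  m <- vapply(score_tables, function(s) {
    stopifnot(identical(s$gene_id, ids))
    as.numeric(s[[kind]])
  }, numeric(length(ids)))
  rownames(m) <- ids
  m
}
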