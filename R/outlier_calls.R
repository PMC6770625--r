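# Outlier calling on the (GRE, NGRE) or (PII, NPII) scatter: one-parameter
# least squares through the origin, then per-side selection of the points
# with the largest Euclidean (perpendicular) distance to the fitted line.

#' Fit a one-parameter regression through the origin
#'
#' Least squares for the model `y = a * x` with no intercept:
#' `a = sum(x * y) / sum(x^2)`.
#'
#' @param x,y finite numeric vectors of equal length (missing-value rows
#'   must be excluded by the caller; [select_outliers()] does so).
#' @return an object of class `origin_fit` with elements `slope`,
#'   `n_points`, `x`, `y`.
#' @seealso [signed_distance()], [select_outliers()]
#' @export
fit_origin_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite; exclude missing values upstream",
         call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x are zero: slope undefined", call. = FALSE)
  structure(list(slope = sum(x * y) / sxx, n_points = length(x),
                 x = x, y = y),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat("Regression through the origin (y = a*x)\n")
  cat(sprintf("  slope a = %.6g   (n = %d points)\n", x$slope, x$n_points))
  invisible(x)
}

#' @export
coef.origin_fit <- function(object, ...) c(slope = object$slope)

#' @export
predict.origin_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$slope * x
}

#' @export
fitted.origin_fit <- function(object, ...) object$slope * object$x

#' @export
residuals.origin_fit <- function(object, ...) object$y - object$slope * object$x

#' Signed Euclidean distance to the fitted line
#'
#' Perpendicular distance of `(x, y)` to the line `y = a*x`:
#' `(y - a*x) / sqrt(1 + a^2)`, positive above the line, negative below,
#' zero on it.
#'
#' @param x,y coordinates.
#' @param slope_a finite slope of the line through the origin.
#' @return numeric vector of signed distances, in score units.
#' @export
signed_distance <- function(x, y, slope_a) {
  stopifnot(is.finite(slope_a))
  (y - slope_a * x) / sqrt(1 + slope_a^2)
}

#' Call RRE-enriched and RRE-deficient outliers
#'
#' Fits `y = a*x` through the origin, computes signed Euclidean distances,
#' and labels the `floor(fraction * n)` most-positive-distance points on the
#' above side and the same number of most-negative-distance points on the
#' below side; everything else is background. Rows with missing `x` or `y`
#' are excluded before fitting and `n` is the post-exclusion count. Ties at
#' the boundary distance are broken by ascending `item_id`; the above-side
#' set is taken first and the below-side set from the remaining points, so
#' degenerate inputs (e.g. all points on the line) still yield disjoint,
#' deterministic call sets.
#'
#' The `direction` argument maps sides to labels. `"as_printed"` labels
#' below-line points RRE_enriched and above-line points RRE_deficient;
#' `"high_y_enriched"` is the inverse mapping, under which a point lying
#' above the trend (more normalized RE-linked signal than its total
#' coverage predicts) is called RRE_enriched.
#'
#' @param items data.frame with columns `item_id`, `x`, `y`.
#' @param fraction selection fraction per side, in (0, 0.5); default 0.05.
#' @param direction `"as_printed"` or `"high_y_enriched"`.
#' @return an object of class `rre_calls`: the input rows (missing excluded)
#'   with `signed_distance` and `label` columns, plus attributes `model`
#'   (the `origin_fit`) and `k` (calls per side).
#' @export
select_outliers <- function(items, fraction = 0.05,
                            direction = c("as_printed", "high_y_enriched")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(items),
            all(c("item_id", "x", "y") %in% names(items)))
  if (!(fraction > 0 && fraction < 0.5))
    stop("fraction must be in (0, 0.5)", call. = FALSE)
  keep <- is.finite(items$x) & is.finite(items$y)
  pts <- items[keep, c("item_id", "x", "y")]
  n <- nrow(pts)
  if (n < ceiling(1 / fraction))
    stop("too few points after missing-value exclusion (", n, ")",
         call. = FALSE)
  model <- fit_origin_regression(pts$x, pts$y)
  d <- signed_distance(pts$x, pts$y, model$slope)
  k <- floor(fraction * n)
  lab_above <- if (direction == "as_printed") "RRE_deficient" else "RRE_enriched"
  lab_below <- if (direction == "as_printed") "RRE_enriched" else "RRE_deficient"
  label <- rep("background", n)
  ord_above <- order(-d, pts$item_id)
  above_idx <- ord_above[seq_len(k)]
  label[above_idx] <- lab_above
  remaining <- setdiff(seq_len(n), above_idx)
  ord_below <- remaining[order(d[remaining], pts$item_id[remaining])]
  label[ord_below[seq_len(k)]] <- lab_below
  out <- data.frame(item_id = pts$item_id, x = pts$x, y = pts$y,
                    signed_distance = d, label = label,
                    stringsAsFactors = FALSE)
  structure(out, model = model, k = k, fraction = fraction,
            direction = direction,
            class = c("rre_calls", "data.frame"))
}

#' @export
print.rre_calls <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf(
    "RRE outlier calls: %d points, slope a = %.4g, %d calls per side (%.1f%%)\n",
    nrow(x), m$slope, attr(x, "k"), 100 * attr(x, "fraction")))
  print(table(x$label))
  invisible(x)
}

#' @export
summary.rre_calls <- function(object, ...) {
  m <- attr(object, "model")
  list(slope = m$slope, n_points = nrow(object), k_per_side = attr(object, "k"),
       labels = table(object$label),
       distance_range = range(object$signed_distance))
}

#' Scatter plot of an outlier call set
#'
#' @param x an `rre_calls` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rre_calls <- function(x, ...) {
  col <- c(RRE_enriched = "firebrick", RRE_deficient = "navy",
           background = "grey60")[x$label]
  graphics::plot(x$x, x$y, col = col, pch = 20,
                 xlab = "enrichment score (x)",
                 ylab = "normalized score (y)", ...)
  graphics::abline(0, attr(x, "model")$slope, lty = 2)
  invisible(x)
}
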