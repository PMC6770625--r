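test_that("origin regression slope equals the closed form and a grid search", {
  f <- fit_origin_regression(c(1, 2), c(2, 4))
  expect_equal(unname(coef(f)), 2)
  # inconsistent points: least squares compromise checked against grid search
  f2 <- fit_origin_regression(c(1, 1), c(1, 3))
  expect_equal(f2$slope, 2)
  expect_equal(f2$slope, oracle_slope_grid(c(1, 1), c(1, 3)),
               tolerance = 1e-3)
  f3 <- fit_origin_regression(c(1, 0), c(0, 1))
  expect_equal(f3$slope, 0)
  expect_equal(f3$slope, oracle_slope_grid(c(1, 0), c(0, 1)),
               tolerance = 1e-3)
  set.seed(31)
  x <- runif(40, 0, 3); y <- 1.7 * x + rnorm(40)
  expect_equal(fit_origin_regression(x, y)$slope, oracle_slope_grid(x, y),
               tolerance = 1e-3)
})

test_that("origin fit validates its inputs", {
  expect_error(fit_origin_regression(1, 2), "at least 2")
  expect_error(fit_origin_regression(c(0, 0), c(1, 2)), "all x are zero")
  expect_error(fit_origin_regression(c(1, NA), c(1, 2)), "finite")
})

test_that("origin_fit behaves like a model object", {
  f <- fit_origin_regression(c(1, 2, 3), c(2.1, 3.9, 6.0))
  expect_s3_class(f, "origin_fit")
  expect_equal(predict(f, newdata = 10), f$slope * 10)
  expect_equal(fitted(f) + residuals(f), f$y)
  expect_output(print(f), "slope")
})

test_that("signed distance has the textbook geometry", {
  expect_equal(signed_distance(0, sqrt(2), 1), 1)
  expect_equal(signed_distance(3, 6, 2), 0)
  expect_equal(signed_distance(5, -2, 0), -2)
  # below the line is negative
  expect_lt(signed_distance(2, 1, 1), 0)
})

test_that("outlier selection takes floor(fraction*n) per side", {
  set.seed(32)
  for (n in c(39, 100, 1000)) {
    items <- data.frame(item_id = sprintf("i%04d", 1:n),
                        x = runif(n, 0, 2))
    items$y <- items$x + rnorm(n, 0, 0.3)
    calls <- select_outliers(items, fraction = 0.05)
    k <- floor(0.05 * n)
    expect_equal(sum(calls$label == "RRE_enriched"), k)
    expect_equal(sum(calls$label == "RRE_deficient"), k)
    expect_equal(sum(calls$label == "background"), n - 2 * k)
  }
})

test_that("selection equals the exhaustive sort-by-distance oracle", {
  set.seed(33)
  items <- data.frame(item_id = sprintf("i%03d", 1:200),
                      x = runif(200, 0, 3))
  items$y <- 1.4 * items$x + rnorm(200, 0, 0.5)
  calls <- select_outliers(items, fraction = 0.05, direction = "as_printed")
  # independent oracle: recompute slope and distances directly, sort
  a <- sum(items$x * items$y) / sum(items$x^2)
  d <- (items$y - a * items$x) / sqrt(1 + a^2)
  ord <- order(d, items$item_id)
  k <- 10
  below <- items$item_id[ord[1:k]]
  above <- items$item_id[rev(ord)][1:k]
  expect_setequal(calls$item_id[calls$label == "RRE_enriched"], below)
  expect_setequal(calls$item_id[calls$label == "RRE_deficient"], above)
})

test_that("the direction switch relabels the two sides", {
  set.seed(34)
  items <- data.frame(item_id = sprintf("i%03d", 1:60), x = runif(60, 0, 2))
  items$y <- items$x + rnorm(60, 0, 0.2)
  printed <- select_outliers(items, direction = "as_printed")
  coherent <- select_outliers(items, direction = "high_y_enriched")
  expect_setequal(printed$item_id[printed$label == "RRE_deficient"],
                  coherent$item_id[coherent$label == "RRE_enriched"])
  expect_setequal(printed$item_id[printed$label == "RRE_enriched"],
                  coherent$item_id[coherent$label == "RRE_deficient"])
})

test_that("points on the line are split deterministically by item id", {
  items <- data.frame(item_id = sprintf("i%02d", 1:40), x = 1:40)
  items$y <- 2 * items$x
  calls <- select_outliers(items, fraction = 0.05, direction = "as_printed")
  expect_equal(sort(calls$item_id[calls$label == "RRE_deficient"]),
               c("i01", "i02"))
  expect_equal(sort(calls$item_id[calls$label == "RRE_enriched"]),
               c("i03", "i04"))
  # the two call sets never overlap
  expect_equal(anyDuplicated(calls$item_id[calls$label != "background"]), 0L)
})

test_that("missing scores are excluded and n reflects the exclusion", {
  items <- data.frame(item_id = sprintf("i%03d", 1:50),
                      x = c(runif(45, 0.5, 2), rep(NA, 5)))
  items$y <- items$x * 1.1
  items$y[3] <- NA
  calls <- select_outliers(items, fraction = 0.1)
  expect_equal(nrow(calls), 44)
  expect_equal(attr(calls, "k"), floor(0.1 * 44))
  expect_error(select_outliers(items[1:8, ], fraction = 0.05), "too few")
  expect_error(select_outliers(items, fraction = 0.6), "fraction")
})

test_that("rescaling x and y together leaves the selected sets unchanged", {
  set.seed(35)
  items <- data.frame(item_id = sprintf("i%03d", 1:150), x = runif(150, 0, 4))
  items$y <- 0.8 * items$x + rnorm(150, 0, 0.4)
  calls <- select_outliers(items)
  scaled <- items
  scaled$x <- scaled$x * 37.5
  scaled$y <- scaled$y * 37.5
  calls2 <- select_outliers(scaled)
  expect_identical(calls$label, calls2$label)
  expect_equal(calls2$signed_distance, 37.5 * calls$signed_distance,
               tolerance = 1e-12)
})
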