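test_that("category assignment maximizes the example-term intersection", {
  cats <- list(A = list(c("g1", "g2")), B = list("g3"))
  expect_equal(assign_to_category(c("g1", "g2", "g3"), cats), "A")
  # lexicographic tie-break
  cats2 <- list(Binfection = list(c("g1")), Aimmunity = list(c("g2")))
  expect_equal(assign_to_category(c("g1", "g2"), cats2), "Aimmunity")
  expect_equal(assign_to_category("gX", cats), "unassigned")
  expect_error(assign_to_category(character(), cats), "empty")
  # multiple example terms per category: the best one counts
  cats3 <- list(A = list("gX", c("g1", "g2", "g3")), B = list(c("g1", "g2")))
  expect_equal(assign_to_category(c("g1", "g2", "g3"), cats3), "A")
})

test_that("EASE p matches hand-computed tables and the x=0 convention", {
  expect_equal(ease_p(0, 5, 5, 20), 1)
  # x=2,y=2,z=2,k=4: adjusted 1, p = 1 - C(2,0)C(2,2)/C(4,2) = 5/6
  expect_equal(ease_p(2, 2, 2, 4), 5 / 6)
  expect_equal(ease_p(3, 10, 5, 100), oracle_hyper_tail(2, 10, 5, 100))
  expect_error(ease_p(3, 2, 5, 100), "invalid contingency")
  expect_error(ease_p(1, 2, 5, 4), "invalid contingency")
})

test_that("EASE equals the exact tail enumeration and is conservative", {
  set.seed(41)
  for (i in 1:200) {
    k <- sample(2:50, 1)
    y <- sample(0:k, 1)
    z <- sample(0:k, 1)
    x <- sample(0:min(y, z), 1)
    p_ease <- ease_p(x, y, z, k)
    expect_equal(p_ease, oracle_hyper_tail(max(0, x - 1), y, z, k),
                 tolerance = 1e-12)
    # conservative relative to the unadjusted Fisher upper tail
    expect_gte(p_ease, oracle_hyper_tail(x, y, z, k) - 1e-12)
  }
})

test_that("EASE is monotone non-increasing in x", {
  for (tab in list(c(10, 8, 40), c(25, 25, 50), c(5, 30, 35))) {
    y <- tab[1]; z <- tab[2]; k <- tab[3]
    p <- vapply(0:min(y, z), function(x) ease_p(x, y, z, k), 0)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("Fisher's method has its identities and closed forms", {
  expect_equal(fisher_combine(0.05), 0.05)
  expect_equal(fisher_combine(c(1, 1)), 1)
  # two inputs: survival of chi-square(4) is exp(-X2/2) * (1 + X2/2)
  for (pp in list(c(0.1, 0.1), c(0.5, 0.01), c(0.9, 0.2))) {
    x2 <- -2 * sum(log(pp))
    expect_equal(fisher_combine(pp), exp(-x2 / 2) * (1 + x2 / 2),
                 tolerance = 1e-10)
  }
  expect_equal(fisher_combine(c(0.3, 0.02, 0.7)),
               fisher_combine(c(0.7, 0.3, 0.02)))
  expect_error(fisher_combine(numeric()), "no p-values")
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  expect_warning(p <- fisher_combine(c(1e-310, 0.5)), "clipped")
  expect_true(p > 0 && p < 1)
})

test_that("Fisher's method is monotone in each input", {
  base <- c(0.2, 0.4, 0.6)
  p0 <- fisher_combine(base)
  for (i in 1:3) {
    lower <- base; lower[i] <- lower[i] / 2
    expect_lt(fisher_combine(lower), p0)
  }
})

make_gene_calls <- function(universe, enriched, deficient) {
  structure(data.frame(
    item_id = universe,
    x = 1, y = 1, signed_distance = 0,
    label = ifelse(universe %in% enriched, "RRE_enriched",
                   ifelse(universe %in% deficient, "RRE_deficient",
                          "background")),
    stringsAsFactors = FALSE), class = c("rre_calls", "data.frame"))
}

test_that("gene-level table builds the documented contingency and aggregates", {
  universe <- sprintf("g%02d", 1:40)
  calls <- make_gene_calls(universe, enriched = universe[1:5],
                           deficient = universe[36:40])
  terms <- list(
    list(pathway_id = "T1", genes = universe[1:5]),   # fully in enriched set
    list(pathway_id = "T2", genes = universe[10:19]),
    list(pathway_id = "T3", genes = "ghost"))
  cats <- list(catA = list(universe[1:10]), catB = list(universe[11:30]))
  expect_warning(
    tab <- gene_level_category_table(calls, terms, universe, cats),
    "no genes")
  # T1: x=5, y=5, z=5, k=40 -> direct hypergeometric with the EASE shift
  a_up <- tab$p_gene[tab$category == "catA" & tab$direction == "up"]
  expect_equal(a_up, oracle_hyper_tail(4, 5, 5, 40))
  # single term in catB: Fisher aggregation of one p is that p
  b_up <- tab$p_gene[tab$category == "catB" & tab$direction == "up"]
  expect_equal(b_up, ease_p(0, 5, 10, 40))
  # categories with no assigned terms are omitted
  expect_setequal(unique(tab$category), c("catA", "catB"))
  expect_true(all(tab$ranking_only))
})

test_that("term category overrides replace the automatic assignment", {
  universe <- sprintf("g%02d", 1:20)
  calls <- make_gene_calls(universe, universe[1:2], universe[19:20])
  terms <- list(list(pathway_id = "T1", genes = universe[1:4]))
  cats <- list(catA = list(universe[1:4]), catB = list(universe[5:8]))
  tab <- gene_level_category_table(calls, terms, universe, cats,
                                   overrides = c(T1 = "catB"))
  expect_equal(unique(tab$category), "catB")
})

test_that("pathway-level table counts categories correctly", {
  pws <- sprintf("P%02d", 1:20)
  pc <- setNames(rep(c("catA", "catB"), each = 10), pws)
  calls <- make_gene_calls(pws, enriched = pws[1:4], deficient = pws[11:12])
  tab <- pathway_level_category_table(calls, pc)
  rowA <- tab[tab$category == "catA" & tab$direction == "up", ]
  expect_equal(c(rowA$x, rowA$y, rowA$z, rowA$k), c(4, 4, 10, 20))
  expect_equal(rowA$p_pathway, oracle_hyper_tail(3, 4, 10, 20))
  row0 <- tab[tab$category == "catB" & tab$direction == "up", ]
  expect_equal(row0$p_pathway, 1)  # x = 0
})

test_that("combining gene and pathway p-values delegates and propagates NA", {
  gt <- data.frame(category = c("A", "B"), direction = "up",
                   p_gene = c(0.1, 0.2))
  pt <- data.frame(category = "A", direction = "up", p_pathway = 0.1)
  comb <- combine_gene_pathway(gt, pt)
  a <- comb[comb$category == "A", ]
  expect_equal(a$p_combined, fisher_combine(c(0.1, 0.1)))
  expect_true(is.na(comb$p_combined[comb$category == "B"]))
  expect_equal(combine_gene_pathway(
    data.frame(category = "A", direction = "up", p_gene = 1),
    data.frame(category = "A", direction = "up", p_pathway = 1))$p_combined, 1)
})
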