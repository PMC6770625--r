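# Independent brute-force oracles used to validate the production code.
# These deliberately avoid the interval and distribution machinery the
# package itself uses.

# per-base overlap: do [s1, e1) and [s2, e2) share at least one base?
base_overlap <- function(s1, e1, s2, e2) {
  b1 <- seq.int(s1, e1 - 1L)
  any(b1 >= s2 & b1 < e2)
}

# THS oracle: exhaustive per-base scan of every tag against every window
oracle_ths <- function(genes, tags, halfwidth) {
  out <- integer(nrow(genes))
  names(out) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    ns <- max(0L, genes$tss[g] - halfwidth)
    ne <- genes$tss[g] + halfwidth
    for (t in seq_len(nrow(tags))) {
      if (tags$chrom[t] == genes$chrom[g] &&
          base_overlap(tags$start[t], tags$end[t], ns, ne))
        out[g] <- out[g] + 1L
    }
  }
  out
}

# HES oracle: exhaustive enumeration of (tag, RE, gene) triples; a tag
# counts once per gene however many REs it touches
oracle_hes <- function(genes, tags, repeats, halfwidth) {
  out <- integer(nrow(genes))
  names(out) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    ns <- max(0L, genes$tss[g] - halfwidth)
    ne <- genes$tss[g] + halfwidth
    for (t in seq_len(nrow(tags))) {
      if (tags$chrom[t] != genes$chrom[g] ||
          !base_overlap(tags$start[t], tags$end[t], ns, ne)) next
      linked <- FALSE
      for (r in seq_len(nrow(repeats))) {
        if (repeats$chrom[r] == tags$chrom[t] &&
            base_overlap(repeats$start[r], repeats$end[r], ns, ne) &&
            base_overlap(tags$start[t], tags$end[t],
                         repeats$start[r], repeats$end[r])) {
          linked <- TRUE
          break
        }
      }
      if (linked) out[g] <- out[g] + 1L
    }
  }
  out
}

# class-fraction oracle by direct enumeration
oracle_fractions <- function(tags, repeats) {
  n <- nrow(tags)
  touch <- function(sub) {
    vapply(seq_len(n), function(t) {
      any(vapply(seq_len(nrow(sub)), function(r)
        sub$chrom[r] == tags$chrom[t] &&
          base_overlap(tags$start[t], tags$end[t],
                       sub$start[r], sub$end[r]), TRUE))
    }, TRUE)
  }
  classes <- sort(unique(repeats$re_class))
  list(fraction_re_linked = mean(touch(repeats)),
       per_class = vapply(classes, function(cc)
         mean(touch(repeats[repeats$re_class == cc, , drop = FALSE])), 0))
}

# random toy instance on a single short chromosome
random_toy <- function(n_genes = 8, n_res = 25, n_tags = 150,
                       chrom_len = 1e5, halfwidth = 5000) {
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = "toy",
    tss = sample.int(chrom_len, n_genes),
    stringsAsFactors = FALSE)
  rs <- sample.int(chrom_len - 500L, n_res)
  repeats <- data.frame(
    chrom = "toy", start = rs, end = rs + sample(50:500, n_res, TRUE),
    re_class = sample(c("SINE", "LINE", "LTR_ERV"), n_res, TRUE),
    stringsAsFactors = FALSE)
  ts <- sample.int(chrom_len - 200L, n_tags, replace = TRUE)
  tags <- data.frame(
    chrom = "toy", start = ts, end = ts + sample(20:200, n_tags, TRUE),
    mark = "m", cell_line = "l", stringsAsFactors = FALSE)
  list(genes = genes, repeats = repeats, tags = tags, halfwidth = halfwidth)
}

# exact hypergeometric upper tail via binomial coefficients:
# P(W >= a) for W ~ Hypergeometric(k items, z in category, y drawn)
oracle_hyper_tail <- function(a, y, z, k) {
  hi <- min(y, z)
  if (a > hi) return(0)
  w <- seq.int(max(0L, a), hi)
  ok <- (y - w) <= (k - z)
  sum(choose(z, w[ok]) * choose(k - z, y - w[ok])) / choose(k, y)
}

# grid-search minimizer of sum((y - a*x)^2) over a
oracle_slope_grid <- function(x, y, lo = -10, hi = 10, steps = 2e5) {
  a <- seq(lo, hi, length.out = steps)
  sse <- vapply(a, function(ai) sum((y - ai * x)^2), 0)
  a[which.min(sse)]
}
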