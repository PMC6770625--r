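---
title: "Scoring retroelement-linked regulation: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring retroelement-linked regulation: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrospect)
```

## The model

Retroelements (REs) — SINEs, LINEs and LTR retrotransposons / endogenous
retroviruses — occupy a large fraction of mammalian genomes, and every RE
insertion is evolutionarily young relative to the orthologous ancestral
sequence. When a regulatory feature (here, a histone-modification ChIP-seq
tag) sits on RE-derived sequence near a gene's transcription start site,
that feature is a candidate product of recent regulatory innovation. The
per-gene proportion of RE-linked regulatory features is therefore read as a
relative rate of regulatory evolution: genes whose TSS neighborhoods are
unusually rich in RE-linked tags are candidates for fast regulatory
evolution, genes unusually poor in them for slow, conserved regulation.

The unit of evidence is a *tag*: one histone-mark interval for one mark in
one cell line. For each gene we count, in the 10 kb window centred on the
TSS (5 kb upstream + 5 kb downstream, strand-independent):

* `THS` — all tags overlapping the window by at least one base;
* `HES` — tags that additionally overlap at least one RE which itself
  overlaps the window. A tag touching several REs counts once.

Both counts are normalised by their mean over the gene universe of size
$n$:

$$\mathrm{GRE}_g = \frac{\mathrm{HES}_g}{\tfrac1n\sum_i \mathrm{HES}_i},
\qquad
\mathrm{GHE}_g = \frac{\mathrm{THS}_g}{\tfrac1n\sum_i \mathrm{THS}_i},
\qquad
\mathrm{NGRE}_g = \frac{\mathrm{GRE}_g}{\mathrm{GHE}_g}.$$

GRE measures RE-linked regulatory load; GHE the gene's total coverage
trend; NGRE the RE-linked load *relative to* total coverage, which is the
quantity interpreted as the regulatory-evolution rate. Pathway-level
aggregates are plain means over member genes present in the universe:
$\mathrm{PII}_p$ (mean GRE), $\mathrm{PGI}_p$ (mean GHE), and
$\mathrm{NPII}_p = \mathrm{PII}_p / \mathrm{PGI}_p$.

When several cell lines are analysed, each statistic is computed per cell
line and then *averaged across lines per gene or pathway*. The average is
taken over the final statistics, never recomputed from pooled counts, so a
deeply sequenced line cannot dominate the others. Missing values (below)
are excluded from the average and the number of contributing lines is
recorded.

### Conventions and degenerate inputs

* Coordinates are 0-based half-open throughout; BED is native and
  RepeatMasker `.out` (1-based inclusive) is converted on read. Overlap
  means at least one shared base.
* The minus-strand TSS is `end - 1`, the last transcribed base under the
  half-open convention.
* TSS windows clip at position 0; chromosome ends are not clipped because
  chromosome lengths are unknown to the tool.
* A gene with `THS = 0` has `GHE = 0` and its NGRE is *missing*, not zero:
  a zero-coverage gene carries no evidence either way, and treating it as
  zero would flood the deficient tail of the outlier analysis with
  unmeasured genes. Missing NGRE keeps the gene out of outlier calling.
* An all-zero HES (or THS) column is a degenerate-input error: the
  normaliser is undefined.
* The tag-RE overlap in the HES definition is evaluated over the full
  extents of both intervals. The RE must overlap the window, but the
  shared bases between tag and RE may fall outside it. This is one of two
  defensible readings of "REs overlapping the 10 kb region"; it is the
  package's recorded choice, not an inference about anyone's intent.

## Outlier calling

Genes are plotted as (GRE, NGRE) points — pathways as (PII, NPII) — and a
one-parameter regression through the origin, $y = ax$ with
$\hat a = \sum x_i y_i / \sum x_i^2$, captures the bulk trend. Each point's
signed perpendicular (Euclidean) distance to the line,
$(y - \hat a x)/\sqrt{1 + \hat a^2}$, ranks it against the trend; the
`floor(0.05 n)` most-positive and most-negative points are called outliers,
everything else is background. Points with missing NGRE/NPII are excluded
before the fit and `n` is the post-exclusion count. Ties at the boundary
break by ascending item id; the above-line set is selected first and the
below-line set from the remainder, so even an all-on-the-line input yields
disjoint, reproducible call sets.

One genuinely open design point is the direction-to-label map. The source
description of the method labels *bottom* outliers RRE-enriched and *top*
outliers RRE-deficient, while its own reading of the scores is that high
NGRE means strong RE-linked impact — under which an above-trend point
(more normalized RE-linked signal than its coverage predicts) should be
the *enriched* one. `select_outliers()` offers both (`"as_printed"` and
`"high_y_enriched"`) and defaults to the printed mapping. The *pipeline*
default is `"high_y_enriched"`, because on synthetic data with planted
high-NGRE genes only that mapping makes the enriched call set recover the
planted set — which is what the package's validation measures. Users
reproducing the printed convention can flip `outlier$direction`.

## Category enrichment

Outlier calls are summarised over functional categories in three steps.

1. **Assignment.** Every term or pathway is assigned to the category whose
   example gene set shares the most genes with it; ties break to the
   lexicographically smallest category name, and a zero intersection with
   every example yields `"unassigned"`. Manual curation of
   misassignments is supported as an explicit override table
   (`term_id -> category`) rather than an interactive step.
2. **Per-set p-values.** Enrichment of a call set (enriched or deficient
   side separately, labelled up/down) in a gene set uses the EASE score: a
   one-tailed hypergeometric upper tail in which the observed overlap `x`
   is replaced by `max(0, x - 1)`. The decrement makes single-gene
   overlaps worthless (p = 1) and every p-value conservative relative to
   the plain Fisher exact tail. The background is always the entire
   analyzed universe. At the pathway level the same table is applied to
   pathway counts per category directly.
3. **Aggregation.** Per category and side, term p-values are combined by
   Fisher's method, $X^2 = -2\sum \ln p_i \sim \chi^2_{2k}$; the gene- and
   pathway-level category p-values are combined the same way. Inputs below
   `fisher_epsilon` (default 1e-300) are clipped with a warning to keep
   $X^2$ finite.

No multiple-testing correction is applied anywhere, deliberately:
categories share genes and are far from independent, so corrected
thresholds would be misleading. Every output row carries a
`ranking_only = TRUE` flag — the p-values order categories; they are not
significance claims.

## Profile correlation and biclustering

A *profile* is a per-gene vector over the universe — by default the GRE
vector of one mark in one cell line, switchable to NGRE or raw THS, since
the appropriate choice of quantity is not settled. Pairwise Pearson
correlation (Spearman available) with pairwise-complete gene handling
yields a symmetric matrix with unit diagonal; a pair with fewer than three
complete genes, or a constant profile, gives a missing entry with a
warning. "Biclustering" of a symmetric correlation matrix is implemented
as average-linkage agglomerative clustering on the distance $1 - c$;
labels are sorted before clustering so merge order and tie-breaking do not
depend on input column order. The dendrogram is exported as newick text.

Expression profiles are correlated with score profiles the same way and
annotated with the mark group (active / repressive) so the expected sign
pattern — positive for open-chromatin marks, negative for heterochromatin
marks — can be read off directly.

## The synthetic-data generator

Because the real inputs (ENCODE ChIP-seq, UCSC annotations, curated
pathway databases) need downloads and genome-scale processing, the package
ships a generator that emulates their *structure* at desk scale and plants
known signal so every stage can be validated end to end. The generator's
defaults are the package's reference study conditions.

**Genome layout.** Genes occupy disjoint 15 kb slots (TSS jittered within
the slot) on a small number of synthetic chromosomes, so TSS windows never
overlap and per-gene truth is unambiguous. Real genomes have overlapping
and nested gene neighborhoods; the counting code supports them (a tag may
count for several genes), but the planted-truth benchmark deliberately
avoids them.

**Retroelements.** Per chromosome and class, interval counts are Poisson
with density 8 per 10 kb split 0.65 / 0.25 / 0.10 over SINE / LINE /
LTR_ERV, with class-typical lengths (SINE 150–350 bp, LINE 0.5–2.5 kb
truncated, LTR/ERV 0.3–1.2 kb). After within-class overlap pruning this
covers roughly 40% of the sequence, comparable to the RE content of the
human genome. Classes may overlap each other, so the rule that one tag
overlapping several REs counts once — and counts for every class it
touches in the class-fraction report — is exercised.

**Tag depth.** Per gene, mark and cell line, total tag counts are negative
binomial (size 8; a Poisson toggle via `tag_dispersion = Inf` exists for
analytic checks) around a mean of 40 times three per-gene factors shared
across cell lines:

* a promoter-strength factor, lognormal with sdlog 0.8 — promoter ChIP
  coverage varies by orders of magnitude across real genes, and this
  heterogeneity is what makes the origin-regression geometry behave as it
  does on real scatters (with homogeneous depth all genes collapse onto
  the trend line and distance-based outlier calling has nothing to rank);
* a pathway co-regulation factor, lognormal with sdlog 0.6, shared by the
  members of a pathway — pathways behave as co-expression modules, and
  without between-pathway coverage variation pathway-level points would
  all hug the trend line;
* an activity tilt, lognormal with sdlog 0.7, entering with exponent +1
  for active marks and −1 for repressive marks. This single factor
  generates the two anticorrelated mark groups; it is centred so both
  groups keep the same expected depth.

**Tag placement.** Each tag of gene *g* is RE-linked with the gene's
planted fraction: 0.8 for the 100 planted enriched genes, 0.05 for the 100
planted deficient genes, 0.2 for the background (the enriched >
background > deficient ordering is validated at construction). RE-linked
tags are placed uniformly over positions overlapping a sampled RE inside
the window; background tags are placed uniformly and re-sampled up to 30
times to avoid REs. A window that contains no RE at all (rare at the
default density, probability about $e^{-7}$ per window) falls back to
background placement with a logged count, so a handful of planted genes
per large run may carry no RE-linked signal — visible as a small recall
loss, not an error.

**Gene sets and expression.** Pathways (100, sizes 8–20) include 10
planted pathways drawing 80% of members from the planted enriched genes;
GO-like terms (40, sizes 15–40) include 8 planted terms built the same
way; category example sets are one planted-module exemplar plus three
disjoint background modules. Expression per cell line is
`active-THS sum − repressive-THS sum` plus Gaussian noise at 0.3 of the
signal sd, so active-mark profiles correlate positively and
repressive-mark profiles negatively with expression by construction.
Setting both couplings to zero gives a pure-noise control; setting the
planted fractions equal to the background gives a calibration/null dataset
in which truth labels exist but carry no signal.

Truth tables (`truth_genes.tsv`, `truth_sets.tsv`) are written for
validation only; no pipeline stage reads them. All outputs are
byte-identical for identical seed and configuration.

**What passing these tests does and does not show.** The generator
reproduces the structural features the method depends on — interval
overlap geometry, overdispersed depth, coverage heterogeneity, two mark
groups, planted set structure — but not read-level artefacts
(mappability, GC bias, peak shape, duplicate reads), not overlapping gene
neighborhoods, not the GO graph (terms are flat gene sets), and not
realistic pathway overlap structure. Recovery of planted signal here
validates the pipeline's logic, not the biological claims one might draw
from any particular real dataset.

## Validation scales and numerical choices

The shipped tests run the full pipeline at the reference conditions (2000
genes, 5 marks × 5 cell lines, about 2 million tags) once and reuse the
result across checks; structural tests use a 150-gene configuration.
Counting is validated against per-base brute-force oracles on randomized
≤100 kb instances; the EASE implementation against exact
binomial-coefficient tail sums over every contingency table with a
universe up to 50; the regression slope against grid-search minimization;
Fisher's method against the closed-form df = 4 survival function.

Score tables are written as TSV with 17 significant digits so re-reading
reproduces every double bit-exactly. Score identities (mean GRE = mean
GHE = 1; NGRE·GHE = GRE where defined) hold to 1e-12 and are asserted at
that tolerance. The mean-normalisation makes all scores scale-free:
multiplying every count by a constant changes nothing downstream.

## Known limitations

* Genes are matched to sets by exact id; alias resolution is the user's
  responsibility.
* The EASE/Fisher machinery assumes term p-values are independent within a
  category, which gene sharing violates — hence the ranking-only flag.
* The outlier fraction is global per scatter; no per-mark adaptation.
* No variance estimates accompany the scores; the method defines none.
* The "biclustering" is one-mode hierarchical clustering of a symmetric
  matrix, chosen for determinism and interpretability; two-mode methods
  are out of scope.
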