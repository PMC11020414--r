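---
title: "Mapping annotated literature corpora with batch self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping annotated literature corpora with batch self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsom)
```

## The problem

Large bibliographic databases annotate every article with terms from a
hierarchical controlled vocabulary (Medline's MeSH is the canonical
example).  Encoding each article as a sparse binary vector over the
vocabulary — one column per retained term, a handful of ones per article —
turns the whole database into a point cloud in a very high-dimensional
hypercube.  A self-organizing map (SOM) fits a low-dimensional grid of
prototype vectors to that cloud so that nearby grid nodes hold similar
prototypes, giving a two-dimensional "map of the literature" on which any
document set can be placed.

`medsom` implements this pipeline end to end at configurable scale: corpus
encoding, batch SOM training with topographic-error model selection,
domain/non-domain node classification, projection of document sets,
k-means clustering of the projected positions with elbow-based selection
of the cluster count, cluster characterization, and cross-edition overlap
summaries.  A reference-matching module and an edition-statistics module
support the validation design in which the independently chosen document
sets are the reference lists of successive editions of a textbook, and a
seeded synthetic-data generator makes the whole pipeline testable offline.

## Corpus encoding

A vocabulary is an *ordered* list of terms with dot-separated tree-number
paths.  Terms whose paths start with a configured prefix (for example the
subtree gathering psychiatric headings) carry an `is_domain` flag.
Administrative terms are excluded at read time, and `filter_rare_terms()`
drops terms annotating fewer than `min_term_count` articles (default 100,
the value used at full literature scale) before training; records left
without annotations are dropped and reported, since training on all-zero
vectors is meaningless.  Column order is construction order, never sorted,
so codebooks are reproducible.

At full scale the numbers are concrete: with D = 29,917 retained terms and
a typical 9 annotations per article, each row of the document-term matrix
has 29,908 zeros.  The matrix is held as a sparse `dgCMatrix` throughout.

## Batch training

Articles live on a grid of R x C nodes (M = R·C; 350 x 350 = 122,500 at
full scale), each node j holding a weight vector w_j of length D.  One
batch epoch does, with all BMU queries against the *pre-epoch* codebook:

1. assign every article x_i its best matching unit (BMU)
   b(i) = argmin_j ||x_i − w_j||²;
2. accumulate S_j = Σ_i h(b(i), j) · x_i and Z_j = Σ_i h(b(i), j), where
   h(b, j) = exp(−d(b, j)² / 2σ_e²) and d is Euclidean distance between
   grid coordinates (a bubble kernel, h = 1 within radius σ_e, is
   available via config);
3. replace w_j by S_j / Z_j at epoch end; nodes with Z_j ≤ 1e−12 keep
   their weights (dead-node rule, avoiding 0/0 without resampling).

Because assignments are frozen for the whole epoch, the update is
invariant to article order; and because every new weight is a convex
combination of binary inputs, weights stay in [0, 1] forever — both are
tested properties.  BMU search expands
||x − w||² = ||x||² + ||w||² − 2 x·w so the sparse input is touched only
at its nonzeros; ties break to the lowest linear node index, and the
second BMU excludes only the first.

The neighborhood width shrinks geometrically, σ(e) = σ0 / 1.7^e for epoch
e = 1..20, with σ0 conventionally half the grid side (175 on the 350
grid).  The first epoch therefore already trains below σ0, and the width
drops under one grid unit around epoch 10 — the exact crossing is
computed, not assumed, in the tests.

Codebooks are initialized from uniformly sampled article vectors (seeded),
with ±1e−3 jitter to break exact ties, clamped back to [0, 1].  Random
initial weights would be pathological BMU targets for binary data:
sampled articles start every node inside the data's support.

After each epoch the *topographic error* — the fraction of articles whose
first and second BMUs are not adjacent (8-neighborhood by default,
4-neighborhood via config) — is recorded, and the codebook with the
lowest value across epochs is selected (earliest epoch on ties).  Training
is bit-reproducible for a fixed seed.

Nodes are classified as domain-positive when the mean weight over
in-domain vocabulary columns strictly exceeds the mean over the remaining
columns; a perfectly uniform node is therefore non-domain, and a
vocabulary without domain terms makes the classification an error rather
than a silent constant.

## The interpretive layer

`project_corpus()` maps every article of a document set to its BMU
coordinates and tallies a per-node density grid.  `kmeans_grid()` then
clusters the raw (row, col) positions — duplicates retained, each article
counts — with Lloyd iterations, k-means++ seeding, a configurable number
of seeded restarts (default 10), and empty-cluster repair by moving the
empty center onto the point farthest from its current center.  The spec of
this operation (deterministic seeding, restart policy, repair and tie
rules) is not expressible through `stats::kmeans`, so the loop is
implemented here and `stats::kmeans` serves as an independent cross-check
in the tests, alongside an exhaustive-assignment oracle on tiny instances.

The cluster count is chosen with the elbow rule operationalized as maximum
perpendicular distance from the WSS curve to the chord joining its first
and last points (k_max defaults to 12 — double the six clusters the
motivating validation found — and flat or linear curves return k = 1 with
a warning).  A forced-k mode reproduces a fixed layout on demand.

Each cluster is characterized by its ten most frequent terms (ties broken
alphabetically by label) and its ten exemplar articles — those carrying
the most of the top terms, ties broken by ascending article id, so the
output is invariant to input order.  Per-cluster 95% normal ellipses use
the mean, sample covariance and radial scale sqrt(qchisq(0.95, df = 2))
(≈ √5.99), the standard bivariate-normal construction; collinear clusters
are an explicit error naming the cluster.  `overlap_report()` matches
clusters across editions greedily by centroid distance — a visual
comparison in the motivating study; any automated pairing needs a rule,
and greedy-by-distance is transparent — and reports centroid distances
and Jaccard overlap of occupied node sets.

## Reference matching and edition statistics

Free-text references are parsed heuristically into first-author surname,
title and journal (lower-cased, punctuation-stripped).  A reference
matches a local bibliographic record when it shares the normalized
surname and exactly one candidate exceeds both similarity thresholds
(normalized Levenshtein; defaults 0.90 for titles, 0.80 for journals,
both configurable up to exact equality at 1.0).  None or several passing
candidates reject the reference with a reason code — rejects are data,
mirroring a workflow in which unmatched references are counted as
non-indexed.  Note that the ambiguity rule makes "raising a threshold
never increases matches" a practical rather than a logical guarantee: a
stricter threshold can in principle disambiguate a two-way tie.  The
generator therefore synthesizes records whose titles differ in at least
two content words within a surname, which keeps the monotonicity property
exact on the tested fixtures.

Edition statistics are plain arithmetic with explicit conventions:
citations per chapter = total citations / chapters, rounded half-up to one
decimal; persistence = the percentage of the *current* edition's indexed
citations already present in the previous edition, rounded half-up to a
whole percent (the direction is interpretive but forced by the fact that
the second edition's value can only be measured against the first).
Aggregate means exclude the first edition, which has no predecessor.
Half-up rounding is deliberate: `base::round()` rounds half to even and
disagrees with printed tables on values like 26.5.  The package ships the
ten-edition organizational table of a standard psychiatric textbook as a
fixture (`inst/extdata/ksctp_editions.tsv`); its per-edition column and
the aggregates (7.3 new chapters, 6.3 removed, 26% persistence) are
regression-tested against recomputation.  The source text of that table
states a 55% persistence high for the third edition while the table
itself prints 56%; the fixture stores the printed table value.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised:

* `make_vocabulary(n_terms, n_domain)` builds a hierarchical vocabulary
  with a designated domain subtree (prefix `"F"`).
* `make_corpus()` plants G topics: each article draws a topic uniformly,
  an annotation count from Poisson(9) truncated at 1 (matching an average
  of 9 annotations per article with the simplest documented law), and
  each annotation from its topic's signature with probability 0.9, else
  uniformly from the vocabulary.  Duplicate draws collapse, so distinct
  term counts sit slightly below the Poisson draw.
* Topic signatures are pairwise disjoint with 6 terms each by default.
  The size matters: it controls within-topic diversity on the map.  With
  signatures the annotation budget can fully express (size below the mean
  of 9), same-topic articles are nearly identical, topics form compact
  well-separated clouds on the trained map, and position-space k-means
  recovers them — the regime the recovery properties are stated for.
  With much larger signatures each topic spreads over a broad ragged
  region, projected points tile the whole grid, and clustering positions
  becomes a geometric quantization exercise rather than topic recovery.
* `make_editions()` plants citation persistence: edition 1 is a uniform
  sample, and each later edition keeps its predecessor's ids
  independently with the planted rate, filling to size with fresh ids
  drawn from the corpus *excluding the previous edition*.  The exclusion
  makes the measured persistence an exact binomial draw at the planted
  rate; sampling fills from the whole corpus would add a hypergeometric
  chance overlap (~4–5 percentage points at the tested sizes) on top of
  the planted signal.

What the generator does **not** emulate: real MeSH semantics and term
frequencies (which are heavy-tailed and correlated), hierarchical topic
structure, term drift over decades, and citation-network effects.
Passing recovery tests therefore show that the machinery is correct under
clean planted structure, not that real literature maps are this clean.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: grids up to
20 x 20, corpora up to 2,000 articles over 200 terms, 20 epochs — a full
training run in a few seconds — while the configuration defaults document
the full-scale values (350 x 350, σ0 = 175, 20 epochs, minimum term count
100).  Other fixed choices: BMU and k-means tie-breaks as above; dead-node
ε = 1e−12; WSS monotonicity asserted to 1e−9 (restart noise); codebooks
serialized as a JSON header plus a `%.17g` tab-separated weight block,
which round-trips IEEE doubles exactly in a text-only container; every
stochastic step seeded through a single integer.

## Known limitations

* **Topographic-error model selection can favor over-smoothed codebooks.**
  Early epochs train with a wide neighborhood; the resulting near-uniform
  maps place first and second BMUs trivially adjacent and score
  near-zero topographic error, so the minimum-error rule sometimes
  selects an epoch whose map is smooth rather than organized.  On small
  grids this occasionally costs topic-recovery accuracy (observed on a
  minority of random seeds).  The selection rule is the method's;
  alternatives (quantization error, combined criteria) are deliberately
  not substituted.
* K-means on grid positions assumes compact, roughly isotropic projected
  clouds; elongated or folded SOM regions are split or merged on
  geometric grounds.
* The reference parser handles author–title–journal citations in the
  period-separated form; heavily abbreviated or punctuation-free styles
  are flagged rather than guessed.
* Grid sizes are memory-bound by the M x M neighborhood matrix built per
  epoch; the full 122,500-node scale is supported by the data structures
  but not by this dense kernel path.
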