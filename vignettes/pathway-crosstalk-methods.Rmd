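---
title: "Methods: function-based pathway cross-talk discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: function-based pathway cross-talk discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pathways in a cell are not isolated: they share components, their proteins
interact, and they co-regulate common processes. Statistical tests built on
shared genes or on protein-protein interaction (PPI) counts miss pairs that
interact through few physical links — two pathways can cooperate while
sharing a single gene. `pathcrosstalk` scores pathway pairs by *functional*
similarity instead: two pathways implicated in many of the same biological
processes are candidate cross-talk partners even when they barely touch
physically. The physical tests are included as comparators, and tissue
co-expression provides an orthogonal plausibility check.

## The function-based score (funSim)

For each pathway the package selects **representative GO terms**: every
biological-process term with at least one direct annotation among the
pathway's genes is tested for enrichment against the annotated universe by
a one-sided Fisher exact test (hypergeometric upper tail), p-values are
Benjamini-Hochberg adjusted across exactly the tested terms, and terms with
adjusted p < `alpha` (default 0.05, strict) are kept. Terms with zero
in-pathway count are skipped — they can only dilute the adjustment. The
test universe is the full annotated universe (all genes with at least one
kept biological-process annotation), not the pathway-collection union,
because a pathway is being compared against the genome background.

Each pathway *i* then becomes a sparse TF-IDF vector over the union of
representative terms. The term frequency propagates annotation counts up
the DAG:

    tf_ij = a_ij + sum over descendants t of j of a_it

where `a_ij` is the number of pathway-*i* genes directly annotated to term
*j*. Because a term's meaning includes the meaning of everything below it,
"children" is read **recursively** (all strict descendants) by default; a
`children_mode = "direct"` switch preserves the literal one-level reading.
The default `mode = "sum"` applies the formula literally, so a gene
annotated to several descendants of *j* counts once per descendant;
`mode = "distinct"` counts distinct genes instead. Both are implemented
and tested; `sum` is the default because it is the stated formula, and the
cosine score is insensitive to the difference in practice.

The weight is `w_ij = tf_ij * log(N_G / tf_Gj)` with natural log, where
`N_G` is the annotated-universe size and `tf_Gj` the same propagated
frequency over the whole universe (propagated, to match the pathway-level
frequency; a direct-count variant is available through the same mode
switch). Under `sum` the propagated genome frequency can exceed `N_G`,
which would make the log negative; such weights are clipped to 0 so that
TF-IDF weights stay non-negative and the cosine stays in [0, 1]. The log
base is immaterial: changing it rescales every weight by one positive
constant and leaves every cosine unchanged (this invariance is asserted in
the tests to 1e-12).

The pair score is the cosine

    funSim(p1, p2) = p1 . p2 / (||p1|| ||p2||)

in [0, 1]. A pathway with no representative terms has an empty vector and
scores 0 against everything — never `NaN`. Pairs with funSim strictly
above the cutoff (default 0.5) are **function-related pathway pairs**
(FRPs), the package's cross-talk candidates.

## Null calibration

The cutoff is calibrated against an empirical null: each pathway is
replaced by a random gene set in which every annotated gene is swapped for
a uniformly drawn universe gene with the **same number of directly
annotated terms** (direct counts, because that is what an annotation table
reads off independently of propagation). Draws within one set are without
replacement; unannotated pathway genes are dropped, since they carry no
count to match. Because a count stratum always contains the pathway's own
genes, exact matching cannot be exhausted; a nearest-count fallback exists
for robustness and logs when used. The full pipeline (enrichment, vectors,
cosine) is re-run on each of `n_lists` randomized collections (default
100) and all pair scores are pooled. `fpr_at_cutoff` is the exceedance
fraction of this pool; `cutoff_for_fpr` scans a 0.01 grid for the smallest
cutoff meeting a target rate. Per-list seeds derive deterministically from
one master seed, so the whole null is reproducible.

## The physical comparators

**SOP (significantly overlapping pairs)** — a one-sided Fisher exact test
on the 2x2 membership table of the two gene sets over the collection union
(the union, not the genome, because this is an intra-collection
comparison), BH-adjusted over all pairs; adjusted p < 0.05 flags a SOP.

**SIP (significantly interacting pairs)** — assessed only on non-SOP
pairs. The observed count of PPI edges spanning the two pathways (edges
with both endpoints inside the shared genes are excluded; an edge from a
shared gene to an exclusive gene counts once — a symmetric, documented
convention) is compared against a background from 1,000 randomization
rounds in which each pathway is replaced by an equal-sized uniform draw
from network nodes. The published description of this hybrid
"randomization plus Fisher" construction is incomplete, so the package
emits two p-values: the primary one-sided Fisher test of observed
inter-pathway edges versus the rounded mean background (both against total
edge count), and a secondary add-one empirical percentile. Either reading
can be compared downstream; the Fisher p is BH-adjusted across tested
pairs for the SIP call.

## Tissue co-expression

A pathway is *expressed* in a tissue when its genes are over-represented
among the tissue's expressed genes (hypergeometric upper tail, p < 0.05
strict; expression is presence of at least one EST-style observation, so
count tables and 0/1 tables are both accepted). For a pair, with `E1`,
`E2` expressed-tissue counts and `E12` common tissues, the co-expression
value is the mean of the Jaccard coefficient `E12/(E1+E2-E12)` and the
overlap coefficient `E12/min(E1,E2)` — the average compensates each
coefficient's weakness under imbalanced `E1, E2`. Degenerate denominators
(a pathway expressed nowhere) score 0 rather than `NaN`. A Wilcoxon
rank-sum wrapper compares the value distributions of two prediction sets.

## Curation rules and bookkeeping

GMT collections are filtered the way pathway compendia are curated:
pathways under 5 genes are removed, then any pathway whose gene set is a
subset of a surviving pathway is removed (the larger set survives; among
identical sets the first in file order survives — a deterministic,
documented tie-break; the removal report distinguishes both). Genes absent
from the annotation universe stay in the pathway — they still count for
overlap and PPI tests — but contribute nothing to term counts.
Annotations are kept only under experimental-evidence codes (EXP, IDA,
IPI, IMP, IGI, IEP, IC) with `NOT`-qualified rows dropped. Only `is_a`
edges build the DAG by default (`part_of` is an opt-in flag), obsolete and
foreign-namespace terms are dropped at parse time, and gene identifiers
are opaque case-sensitive strings — identifier mapping is data curation,
not method.

## The synthetic generator

Because the method's interesting behavior depends on structure that real
resources only provide at genome scale, the package ships generators that
plant that structure at desk scale:

* a rooted, layered GO-like DAG (default 60 terms, depth 6) in which at
  least 10% of terms have two parents, so propagation crosses diamond
  motifs;
* heavy-tailed per-gene direct-annotation counts (shifted geometric capped
  at 8; default 300 genes) so the null's count-matching strata are
  non-trivial;
* **latent functional classes**: 25% of genes are split evenly among the
  planted groups, and a class gene concentrates `theme_strength` (default
  0.8) of its annotations inside its group's theme subtree — a compact
  disjoint DAG family of about 4 terms — the way genes acting in one
  process share annotations under that process;
* pathway groups (default 2 groups x 3 pathways of 15-25 genes) drawing
  `theme_strength` of their genes from their group's class; all
  within-group pairs form the ground truth;
* a background PPI network (edge probability 0.01) with boosted wiring
  (0.3) across truth pairs, and a tissue table (20 tissues) in which each
  group owns a tissue block, so truth pairs co-express.

These defaults were chosen once as a realistic desk-scale emulation:
pathway sizes and per-gene annotation counts sit in the range of curated
human signaling pathways and experimentally annotated genes, and the theme
subtree size (~4 terms) mirrors the depth-specific GO neighborhoods that
make a gene set functionally coherent. What the generator does **not**
emulate: real GO's term-count distribution and depth profile, real PPI
degree distributions beyond heavy-tailedness, inter-annotator noise, and
annotation bias toward well-studied genes. Passing tests therefore show
the machinery is correct and that planted functional signal of realistic
strength is recovered — not that any particular real compendium would
yield a particular FRP count.

## Numerical choices and degenerate inputs

* All hypergeometric tails go through `stats::phyper`; oracle tests check
  them against explicit enumeration to 1e-12 for every margin with a
  universe up to 25-30.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` behind a
  validating wrapper; inputs outside [0, 1] are an error.
* Empty vectors, zero-weight terms, empty strata, pathways expressed
  nowhere, pathways with no annotated genes, and empty prediction sets all
  have defined, tested behavior (score 0 / warning / flagged report —
  never an exception deep in a pipeline run).
* Clique enumeration uses `igraph::cliques`; a brute-force subset oracle
  checks it on graphs up to 12 nodes.
* Every random stage takes an explicit seed, sub-seeds are drawn below
  2^31, and run metadata (sidecar JSON) records seed, config echo and
  input checksums — but no timestamps, so identical runs are
  byte-identical.

## Problem sizes used in the test suite

The suite runs the full pipeline on 6-pathway collections over 300-gene
universes (20 replicate seeds for recovery properties), uses 25-list nulls
for calibration checks, 200-400 SIP randomization rounds on toy networks,
and exhaustive oracles at universe sizes up to 30. These sizes were chosen
so the planted effects are detectable with comfortable margin while the
whole suite stays fast enough to run routinely; production-scale constants
(100 null lists, 1,000 SIP rounds) remain the defaults of the user-facing
functions.

## Known limitations

* funSim inherits the quality of the annotation table; sparsely annotated
  pathways get small vectors and conservative scores.
* Cosine over TF-IDF treats representative terms as orthogonal dimensions;
  semantic similarity between *different* GO terms (Resnik/Lin-style) is
  deliberately out of scope.
* The SIP construction is a faithful implementation of an under-specified
  published procedure; both emitted p-values should agree qualitatively,
  and disagreement is a signal to inspect the pair.
* Pathways are gene sets throughout — topology (reaction order, direction)
  is not modeled.
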