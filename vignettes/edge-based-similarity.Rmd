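---
title: "Edge-based disease semantic similarity and lncRNA functional similarity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based disease semantic similarity and lncRNA functional similarity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfunsim)
```

## The model

`lncfunsim` computes similarity in three layers: disease–disease
semantic similarity on an ontology DAG, lncRNA–lncRNA functional
similarity over associated disease groups, and a companion
least-squares predictor that turns both into association scores.

### Disease semantic similarity

The substrate is a rooted DAG of disease terms. Real inputs are MeSH
Category C descriptors, whose tree numbers encode the hierarchy: an
edge p → c exists when some tree number of c extends a tree number of
p by one dot-separated segment, and a descriptor sitting in several
branches receives several parents. Because the category has many
top-level trees, a single virtual root with information content 0 is
added above them.

Every term gets an information content IC(t) = −log p(t), in nats.
The model does not fix what p is; this package defaults to a
**structural** estimate — p(t) is the fraction of terms that are
inclusive descendants of t — because it is self-contained: no external
annotation corpus is needed, and the IC of a term is a pure function
of the DAG. An **annotation** estimate (add-one-smoothed fraction of
associations annotated at or below t) is available via
`compute_ic(dag, "annotation", associations = ...)` for users who
prefer corpus frequencies. Both satisfy IC(root) = 0 and IC
non-decreasing along every edge, because descendant sets nest; that
monotonicity is what makes the three components below non-negative.

The natural log is part of the model definition, not a convention:
the similarity's second factor 1/(1 + γ) is not invariant to
rescaling γ, so changing the log base changes SS.

For a term pair (a, b), with DIST(x, y) = |IC(x) − IC(y)|:

* **MICA** — the common ancestor of a and b with maximal IC. Each
  term counts among its own ancestors, so for an ancestor/descendant
  pair the MICA is the ancestor and a term compared with itself is its
  own MICA. α = IC(MICA).
* **MIL** — the maximal-IC leaf descending from a term; a leaf is its
  own MIL. β = (DIST(a, MIL_a) + DIST(b, MIL_b))/2 measures how far
  each query term sits above its deepest specialization.
* γ = DIST(MICA, a) + DIST(MICA, b) measures how far the pair sits
  from its shared ancestry.

These combine as SS(a, b) = α/(α + β) · 1/(1 + γ). Two identities pin
the ends of the scale and are tested exactly: a leaf against itself
has β = γ = 0 and SS = 1, and a pair whose only common ancestor is the
root has α = 0 and SS = 0. The α = 0 rule is applied before the ratio,
so the degenerate α = β = 0 case (root against itself in a trivial
DAG) is also 0 — terms with no informative shared ancestry share
nothing.

Two readings of the definition were genuinely open and are resolved
as follows. First, "smallest IC-based distance" selects the MICA and
MIL: we select by **maximal IC**, which is the same thing measured
from the root (for the MICA, distance from the query pair's IC level;
for the MIL, distance from its anchor term) and is the only reading
consistent with α = DIST(ROOT, MICA) = −log p(MICA). Second, γ's
distance is taken to be the same IC-based distance used everywhere
else; an edge-count (shortest-path) variant is available behind
`dist_method = "edges"` for sensitivity analysis and is off by
default.

Tie-breaking for MICA and MIL is lexicographic by term ID. Tied
candidates have equal IC by construction, so ties never change SS,
but the reported component nodes must be deterministic across
platforms. Leaf and root tests are structural (out-degree 0, the
designated root), never via floating-point IC comparisons.

### lncRNA functional similarity

Each lncRNA i is represented by its associated disease group G(i).
With best match S(d, G) = max over d′ in G of SS(d, d′), the
functional similarity is

FS(i, j) = (Σ_{d∈G(i)} S(d, G(j)) + Σ_{d∈G(j)} S(d, G(i))) /
(|G(i)| + |G(j)|).

FS is symmetric by construction and bounded in [0, 1] because each
best match is. The raw diagonal FS(i, i) equals the mean
self-similarity of the group's diseases, which is below 1 whenever a
group contains internal (non-leaf) terms; since downstream predictors
may expect a unit diagonal, `unit_diagonal = TRUE` optionally
overwrites it, and the default keeps the raw values. Disease groups
are deduplicated by resolved term ID only; lncRNAs whose diseases all
fail to map are dropped from the matrix and reported, while the
library-level pair function treats an empty group as an error (with
an opt-in "return 0 and warn" mode for pipelines).

### Predictor and evaluation

The scorer is a re-implementation of the standard Laplacian
regularized least-squares link predictor for bipartite association
data, stated here in its usual form and exposed so each choice can be
varied:

* Gaussian interaction-profile kernels
  K(u, v) = exp(−γ′ ||y_u − y_v||² / m), with m the mean squared
  profile norm over entities with non-empty profiles and γ′ = 1 by
  default (scale-free bandwidth).
* Integration by entrywise averaging of the ontology-derived
  similarity with the kernel; entries with no ontology value fall
  back to the kernel alone, and an optional precomputed lncRNA
  expression similarity enters an equal-weight average. How the
  original predictor weighted its sources is not published, so the
  simple average is the package's choice and is documented as such.
* In each space, the normalized Laplacian L = I − D^{−1/2} S D^{−1/2}
  (zero-degree rows handled as identity rows) and the closed form
  F = S (S + η L S)⁺ Y, with the Moore–Penrose pseudo-inverse guarding
  rank deficiency; for a full-rank S this minimizes
  ||F − Y||² + η tr(FᵀLF), which is how the tests verify it against a
  generic numerical minimizer. The two spaces combine as
  w·F_l + (1 − w)·F_d with neutral defaults η = 1, w = 0.5.

Evaluation follows the global protocol: in leave-one-out, each known
association is removed in turn, kernels and FS are **recomputed
without it** (a deliberately leaky fast mode exists for smoke tests
and is labelled as such), and the left-out pair is ranked against all
never-known pairs pooled across diseases. The ROC threshold sweeps
the rank cutoff; the AUC is the mean tie-adjusted fraction of
candidates that the left-out pairs outrank, the standard meaning of a
single pooled ranking rather than per-disease ROCs averaged. k-fold
CV partitions the known associations per repetition and reports one
pooled AUC per repetition; only the current test fold is removed from
training, and test pairs are ranked against never-known pairs. The
stand-alone `roc_auc` uses midranks, so tied scores receive half
credit, matching the Mann–Whitney pair-counting definition exactly.

RNG discipline: one integer seed drives everything; repetition r of
seed s re-seeds with s + r, so any single repetition is reproducible
in isolation.

## The synthetic generator

`generate_dag` grows a seeded random tree under a depth cap
(defaults: 60 terms, depth ≤ 6, target branching ≈ 2.5), then adds
extra parents with probability 0.1 per term, sampled from
non-descendants so the graph stays acyclic — emulating the shape and
multi-parenting of a curated disease hierarchy at desk scale.
`generate_associations` plants recoverable structure: lncRNAs
(default 20) are split into 4 modules, each anchored at an internal
DAG term so the module's 4 diseases share a non-root ancestor —
meaning the planted signal is carried by the *semantic* similarity,
not merely by co-annotation, and the tests genuinely exercise the
edge-based model. Within-module associations are drawn at 0.7,
background noise at 0.05, and every lncRNA is guaranteed at least one
association. These defaults are fixed study conditions chosen to
resemble a small curated database (a few hundred associations, sparse
noise) while keeping a full leave-one-out run to seconds; the module
truth labels are emitted for assertions.

What the generator does **not** emulate: real databases' heavy-tailed
degree distributions, disease-name synonymy and mapping loss,
study-bias in which diseases are annotated, and any correlation
between expression similarity and disease sharing. Passing tests
therefore demonstrate that the implementation recovers structure its
model assumes, at these scales — not that the model ranks well on any
particular curated snapshot.

## Numerical and scale choices

* All similarity computations are exact linear algebra / set
  operations; the only numerically delicate step is the pseudo-inverse
  (`MASS::ginv`, SVD-based) in the scorer.
* Kernel distance² is clamped at 0 against tiny negative round-off
  from the inner-product expansion.
* Matrix construction precomputes ancestor sets and MILs once per DAG
  (topological sweeps), so a similarity matrix over a few thousand
  terms is feasible; the test and validation scales are deliberately
  small — DAGs of ≤ 100 terms for the exhaustive oracles (50 random
  DAGs for matrix equivalence), 10 seeds of the default generator for
  leave-one-out signal recovery, 1000 repetitions for the null-AUC
  calibration — sizes at which every brute-force oracle runs in
  seconds.
* Whether a full ontology or only the annotated subgraph is supplied
  changes structural IC values; the package computes on exactly the
  DAG it is given and leaves that choice to the caller.

## Known limitations

* Structural IC inherits the ontology's curation imbalance: heavily
  curated regions have more descendants, hence flatter p and lower IC
  near the top. The annotation-IC option shifts, but does not remove,
  this bias.
* The β component reads a term's generality off its deepest leaf;
  terms in thoroughly subdivided branches thus look more general than
  equally specific terms in shallow branches.
* Disease-name resolution is exact (case-insensitive) matching on
  term ID or name; synonym tables are out of scope, and unmatched
  names are reported rather than guessed.
* The predictor's parameters (η, w, γ′) default to neutral values;
  no claim is made that they match any previously published tuning.
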