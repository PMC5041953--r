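# lncfunsim

Quantifying how functionally similar two long non-coding RNAs (lncRNAs)
are is a prerequisite for inferring lncRNA function and for predicting
new lncRNA–disease associations, but direct functional annotation of
lncRNAs is sparse. `lncfunsim` implements an edge-based route around
that gap, built on the assumption that lncRNAs with similar biological
functions tend to be involved in similar diseases:

1. **Disease semantic similarity on a DAG.** Diseases are organized in
   a rooted directed acyclic graph (e.g. the MeSH Category C
   hierarchy; multi-parenting allowed). Each term gets an information
   content IC(t) = −log p(t) (natural log; by default p(t) is the
   inclusive-descendant fraction of the term set). For a pair of terms
   (a, b) with most informative common ancestor MICA and per-term most
   informative leaves MIL, three components are formed from IC
   distances DIST(x, y) = |IC(x) − IC(y)|:

   - α = IC(MICA) — specificity of the shared ancestry,
   - β = (DIST(a, MIL_a) + DIST(b, MIL_b)) / 2 — generality of the
     query terms,
   - γ = DIST(MICA, a) + DIST(MICA, b) — how far the pair sits from
     its shared ancestor,

   combined as **SS(a, b) = α/(α + β) · 1/(1 + γ)** ∈ [0, 1]. SS = 1
   exactly for a leaf compared with itself; SS = 0 exactly when the
   pair meets only at the root.

2. **lncRNA functional similarity.** Each lncRNA i is represented by
   its disease group G(i). With best match
   S(d, G) = max_{d′∈G} SS(d, d′), the functional similarity is the
   normalized two-way best-match sum
   **FS(i, j) = (Σ_{d∈G(i)} S(d, G(j)) + Σ_{d∈G(j)} S(d, G(i))) /
   (|G(i)| + |G(j)|)**.

3. **Prediction and evaluation.** A companion scorer turns
   similarities into association scores: Gaussian interaction-profile
   kernels from the binary association matrix, entrywise-average
   integration with SS/FS, and a Laplacian-regularized least-squares
   solution F = S(S + ηLS)⁺Y in both the lncRNA and disease spaces,
   combined with weight w. Global leave-one-out and repeated k-fold
   cross-validation with ROC/AUC measure how much signal the
   similarity carries. A synthetic generator produces disease DAGs and
   association tables with planted lncRNA modules so the whole chain
   is testable without any external download.

## Worked example

A six-term DAG — root `R` with children `A`, `B`; leaves `C`, `D`
under `A` and `E` under `B`:

```r
library(lncfunsim)
toy <- build_dag_from_edges(cbind(c("R","R","A","A","B"),
                                  c("A","B","C","D","E")))
ic <- compute_ic(toy)
round(ic$ic, 4)
#>      A      B      C      D      E      R
#> 0.6931 1.0986 1.7918 1.7918 1.7918 0.0000

semantic_similarity(toy, ic, "C", "D")   # siblings under A
#> [1] 0.3127713
semantic_similarity(toy, ic, "C", "E")   # meet only at the root
#> [1] 0
ss <- semantic_similarity_matrix(toy, ic)
fs <- functional_similarity_matrix(
  ss, data.frame(lncrna = c("l1","l2","l3"),
                 disease = c("C","D","E")))
round(fs, 4)
#>        l1     l2 l3
#> l1 1.0000 0.3128  0
#> l2 0.3128 1.0000  0
#> l3 0.0000 0.0000  1
```

`C` and `D` share the ancestor `A` (α ≈ 0.693) and are both leaves
(β = 0), at summed IC-distance γ ≈ 2.197 from `A`, giving
SS ≈ 0.313; the lncRNAs annotated to them inherit exactly that
functional similarity, while the lncRNA annotated to the other branch
gets 0.

An end-to-end synthetic run:

```r
dag <- generate_dag(seed = 1)
ss  <- semantic_similarity_matrix(dag, compute_ic(dag))
adj <- association_matrix(generate_associations(dag, seed = 1))
cv  <- global_loocv(adj, ss)
cv$mean_auc
#> [1] 0.7455505
```

with planted module structure recovered well above the chance AUC of
0.5.

A thin command-line wrapper covering the same stages (`build-dag`,
`disease-sim`, `lncrna-sim`, `predict`, `evaluate`, `simulate`) is
installed at `inst/cli/lncfunsim`.

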