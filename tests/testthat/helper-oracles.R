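# Shared fixtures and independent brute-force oracles.
#
# TOY6: the worked 6-term fixture
#        R
#       / \
#      A   B
#     / \   \
#    C   D   E
# Structural IC (denominator 6): ic(R)=0, ic(A)=-log(3/6),
# ic(B)=-log(2/6), ic(C)=ic(D)=ic(E)=-log(1/6).

toy6_dag <- function() {
  build_dag_from_edges(cbind(c("R", "R", "A", "A", "B"),
                             c("A", "B", "C", "D", "E")))
}

# frozen expected values, derived by hand from the structural IC above
TOY6 <- list(
  ic_A = 0.693147180559945, ic_B = 1.09861228866811,
  ic_leaf = 1.79175946922806,
  ss_CD = 0.312771272649591,  # 1 / (1 + 2*log(3))
  ss_AA = 0.386852807234542,  # log(2) / log(6)
  fs_C_D = 0.312771272649591)

# independent ancestor oracle: igraph reachability, not the package's
# adjacency-list walk
oracle_ancestors <- function(dag, id, inclusive = TRUE) {
  g <- igraph::graph_from_data_frame(as.data.frame(dag_edges(dag)),
                                     directed = TRUE,
                                     vertices = dag$term_id)
  anc <- igraph::subcomponent(g, id, mode = "in")$name
  sort(if (inclusive) anc else setdiff(anc, id))
}

oracle_descendants <- function(dag, id) {
  g <- igraph::graph_from_data_frame(as.data.frame(dag_edges(dag)),
                                     directed = TRUE,
                                     vertices = dag$term_id)
  sort(igraph::subcomponent(g, id, mode = "out")$name)
}

oracle_leaves_under <- function(dag, id) {
  desc <- oracle_descendants(dag, id)
  is_leaf <- vapply(desc, function(d) length(dag$children[[d]]) == 0L, NA)
  sort(desc[is_leaf])
}

# brute-force structural IC: inclusive descendant counts via igraph
oracle_ic <- function(dag) {
  real <- if (dag$virtual_root) setdiff(dag$term_id, dag$root) else dag$term_id
  cnt <- vapply(dag$term_id, function(t)
    length(intersect(oracle_descendants(dag, t), real)), 0L)
  p <- pmin(cnt / length(real), 1)
  p[dag$root] <- 1
  -log(p)
}

# brute-force semantic similarity: exhaustive MICA/MIL search from the
# igraph-based ancestor/leaf oracles and an independent IC recomputation
oracle_ss <- function(dag, a, b, ic = oracle_ic(dag)) {
  common <- intersect(oracle_ancestors(dag, a), oracle_ancestors(dag, b))
  mx <- max(ic[common])
  mica <- min(common[ic[common] == mx])
  alpha <- unname(ic[mica])
  if (alpha == 0) return(0)
  mil <- function(t) {
    lv <- oracle_leaves_under(dag, t)
    min(lv[ic[lv] == max(ic[lv])])
  }
  beta <- (abs(ic[a] - ic[mil(a)]) + abs(ic[b] - ic[mil(b)])) / 2
  gamma <- abs(ic[mica] - ic[a]) + abs(ic[mica] - ic[b])
  unname(alpha / (alpha + beta) / (1 + gamma))
}

oracle_ss_matrix <- function(dag) {
  terms <- if (dag$virtual_root) setdiff(dag$term_id, dag$root)
           else dag$term_id
  terms <- sort(terms)
  ic <- oracle_ic(dag)
  m <- matrix(0, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (i in seq_along(terms)) for (j in i:length(terms)) {
    m[i, j] <- m[j, i] <- oracle_ss(dag, terms[i], terms[j], ic)
  }
  m
}

# exhaustive Mann-Whitney pair counting: (concordant + ties/2) / (n+ n-)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# double-loop functional similarity oracle over explicit groups
oracle_fs <- function(ss, gi, gj) {
  bm <- function(d, g) max(ss[d, g])
  (sum(vapply(gi, bm, 0, g = gj)) + sum(vapply(gj, bm, 0, g = gi))) /
    (length(gi) + length(gj))
}

random_dag <- function(seed, n_min = 10L, n_max = 60L) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  generate_dag(n_terms = n, max_depth = sample(3:6, 1L),
               multi_parent_prob = runif(1, 0, 0.3), seed = seed + 1000L)
}
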