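#' Generate a random rooted disease DAG
#'
#' Emulates the shape of a curated disease hierarchy: a seeded random
#' tree grown under a depth cap (each new term attaches to a uniformly
#' chosen existing term of depth below `max_depth`), then extra parents
#' added to non-root terms with probability `multi_parent_prob`,
#' sampled only from non-descendants so acyclicity is preserved.
#' Deterministic per seed.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_depth maximum root-to-term depth (root has depth 0).
#' @param branching_mean target mean number of children per internal
#'   term; controls how wide the tree grows by limiting the pool of
#'   attachment points.
#' @param multi_parent_prob probability in \[0, 1) that a non-root term
#'   receives one extra parent.
#' @param seed integer RNG seed.
#' @return A `disease_dag` with terms T001..Tnnn, T001 the root.
#' @export
generate_dag <- function(n_terms = 60L, max_depth = 6L,
                         branching_mean = 2.5, multi_parent_prob = 0.1,
                         seed = 1L) {
  stopifnot(n_terms >= 2L, max_depth >= 1L, branching_mean > 0,
            multi_parent_prob >= 0, multi_parent_prob < 1)
  if (n_terms < max_depth)
    stop("infeasible: n_terms < max_depth")
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  depth <- setNames(integer(n_terms), ids)
  nkids <- setNames(integer(n_terms), ids)
  parent <- character(0)
  for (i in 2:n_terms) {
    pool <- ids[seq_len(i - 1L)]
    pool <- pool[depth[pool] < max_depth]
    # prefer attachment points with fewer children than the target mean
    wt <- ifelse(nkids[pool] < branching_mean, 1, 0.15)
    p <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = wt)
    parent[i - 1L] <- p
    depth[ids[i]] <- depth[p] + 1L
    nkids[p] <- nkids[p] + 1L
  }
  edges <- cbind(parent, ids[-1L])
  # extra parents: any non-descendant (w.r.t. all edges so far, so
  # acyclicity survives earlier extra edges) not already a parent
  desc_of <- function(id) {
    seen <- id
    frontier <- edges[edges[, 1L] == id, 2L]
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- edges[edges[, 1L] %in% frontier, 2L]
    }
    seen
  }
  for (i in 2:n_terms) {
    if (runif(1) < multi_parent_prob) {
      id <- ids[i]
      forbidden <- c(desc_of(id), edges[edges[, 2L] == id, 1L])
      pool <- setdiff(ids, forbidden)
      if (length(pool))
        edges <- rbind(edges, c(pool[sample.int(length(pool), 1L)], id))
    }
  }
  build_dag_from_edges(edges)
}

#' Generate lncRNA-disease associations with planted modules
#'
#' Partitions lncRNAs round-robin into modules and anchors each module
#' at an internal DAG term with enough descendants, so each module's
#' disease neighborhood shares a non-root ancestor and the planted
#' signal is carried by the semantic similarity, not just
#' co-annotation.  Within-module associations are drawn with
#' `within_module_assoc_prob`, and each lncRNA also picks up noise
#' associations to any module's disease with `noise_assoc_prob`.
#' Every lncRNA is guaranteed at least one association (one
#' within-module association forced when the draws leave it empty).
#' Deterministic per seed.  The ground-truth module assignment of
#' lncRNAs and diseases is attached for test assertions.
#'
#' @param dag a `disease_dag`.
#' @param n_lncrnas number of lncRNAs.
#' @param n_modules number of planted modules.
#' @param diseases_per_module diseases per module neighborhood.
#' @param within_module_assoc_prob association probability inside a
#'   module (must exceed the noise rate: the planted signal).
#' @param noise_assoc_prob background association probability.
#' @param seed integer RNG seed.
#' @return An `association_table` with attributes `lncrna_module`
#'   (named integer) and `disease_module` (named integer).
#' @export
generate_associations <- function(dag, n_lncrnas = 20L, n_modules = 4L,
                                  diseases_per_module = 4L,
                                  within_module_assoc_prob = 0.7,
                                  noise_assoc_prob = 0.05, seed = 1L) {
  stopifnot(n_lncrnas >= 1L, n_modules >= 1L, diseases_per_module >= 1L,
            within_module_assoc_prob > 0, within_module_assoc_prob <= 1,
            noise_assoc_prob >= 0, noise_assoc_prob < 1)
  if (within_module_assoc_prob <= noise_assoc_prob)
    stop("within-module probability must exceed the noise probability")
  set.seed(seed + 1L)
  real <- if (dag$virtual_root) setdiff(dag$term_id, dag$root) else dag$term_id
  # candidate anchors: non-root terms with enough proper descendants
  anchors_all <- real[vapply(real, function(t)
    length(dag_descendants(dag, t, inclusive = FALSE)), 0L) >=
      diseases_per_module]
  anchors_all <- setdiff(anchors_all, dag$root)
  if (length(anchors_all) < n_modules)
    stop("infeasible partition: not enough internal terms with ",
         diseases_per_module, "+ descendants")
  # greedy pick of anchors with disjoint disease neighborhoods
  anchors <- character(0); used <- character(0)
  module_dis <- vector("list", n_modules)
  for (a in sample(anchors_all)) {
    pool <- setdiff(dag_descendants(dag, a, inclusive = FALSE), used)
    if (length(pool) >= diseases_per_module) {
      m <- length(anchors) + 1L
      anchors <- c(anchors, a)
      pick <- sort(pool)[sample.int(length(pool), diseases_per_module)]
      module_dis[[m]] <- sort(pick)
      used <- c(used, pick)
      if (m == n_modules) break
    }
  }
  if (length(anchors) < n_modules)
    stop("infeasible partition: could not find ", n_modules,
         " disjoint module neighborhoods")
  lnc <- sprintf("L%03d", seq_len(n_lncrnas))
  lnc_mod <- setNames(rep_len(seq_len(n_modules), n_lncrnas), lnc)
  all_dis <- unlist(module_dis)
  dis_mod <- setNames(rep(seq_len(n_modules),
                          each = diseases_per_module), all_dis)
  rec <- list()
  for (i in seq_along(lnc)) {
    own <- module_dis[[lnc_mod[i]]]
    hit <- own[runif(length(own)) < within_module_assoc_prob]
    others <- setdiff(all_dis, own)
    hit <- c(hit, others[runif(length(others)) < noise_assoc_prob])
    if (!length(hit)) hit <- own[sample.int(length(own), 1L)]
    rec[[i]] <- data.frame(lncrna = lnc[i], disease = sort(unique(hit)),
                           stringsAsFactors = FALSE)
  }
  out <- normalize_associations(do.call(rbind, rec))
  attr(out, "lncrna_module") <- lnc_mod
  attr(out, "disease_module") <- dis_mod
  out
}

#' Write a complete synthetic workspace
#'
#' Generates a DAG and a planted-module association table and writes
#' them (DAG node/edge tables, association TSV, truth labels TSV) to a
#' directory.
#'
#' @param dir output directory (created if needed).
#' @param dag_params list of arguments for [generate_dag()].
#' @param assoc_params list of arguments for [generate_associations()].
#' @param seed integer seed applied to both generators.
#' @return Invisibly, a list with the generated `dag` and `associations`.
#' @export
simulate_workspace <- function(dir, dag_params = list(),
                               assoc_params = list(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- do.call(generate_dag, c(dag_params, list(seed = seed)))
  assoc <- do.call(generate_associations,
                   c(list(dag = dag), assoc_params, list(seed = seed)))
  write_dag(dag, file.path(dir, "dag"), compute_ic(dag))
  write_associations(assoc, file.path(dir, "associations.tsv"))
  truth <- data.frame(id = c(names(attr(assoc, "lncrna_module")),
                             names(attr(assoc, "disease_module"))),
                      kind = c(rep("lncrna", length(attr(assoc, "lncrna_module"))),
                               rep("disease", length(attr(assoc, "disease_module")))),
                      module = c(attr(assoc, "lncrna_module"),
                                 attr(assoc, "disease_module")))
  write.table(truth, file.path(dir, "truth_modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(dag = dag, associations = assoc))
}
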