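#' @importFrom stats sd setNames rbinom runif quantile
#' @importFrom utils read.table write.table head
NULL

#' Construct a disease DAG from explicit components
#'
#' Low-level constructor shared by the MeSH parser, the edge-list reader
#' and the synthetic generator.  Validates acyclicity and reachability
#' from the root via igraph.
#'
#' @param term_id character vector of unique term identifiers.
#' @param name named character vector of human-readable labels
#'   (names = term_id).
#' @param tree_numbers named list of character vectors of hierarchical
#'   position strings (may be empty for non-MeSH DAGs).
#' @param edges two-column character matrix or data.frame
#'   (parent, child).
#' @param root term_id of the root.
#' @param virtual_root logical; TRUE when the root was synthesised to
#'   join multiple top-level terms.
#' @return An object of class `disease_dag` with fields `term_id`,
#'   `name`, `tree_numbers`, `parents`, `children`, `root`,
#'   `virtual_root`.
#' @keywords internal
new_disease_dag <- function(term_id, name, tree_numbers, edges, root,
                            virtual_root = FALSE) {
  term_id <- as.character(term_id)
  if (anyDuplicated(term_id))
    stop("duplicate term_id: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    storage.mode(edges) <- "character"
    bad <- !(edges %in% term_id)
    if (any(bad))
      stop("edge endpoints not in term set: ",
           paste(unique(edges[bad]), collapse = ", "))
  }
  parents  <- setNames(vector("list", length(term_id)), term_id)
  children <- setNames(vector("list", length(term_id)), term_id)
  for (id in term_id) { parents[[id]] <- character(0); children[[id]] <- character(0) }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1L]; c_ <- edges[k, 2L]
      children[[p]] <- c(children[[p]], c_)
      parents[[c_]] <- c(parents[[c_]], p)
    }
    parents  <- lapply(parents,  function(x) sort(unique(x)))
    children <- lapply(children, function(x) sort(unique(x)))
  }
  dag <- structure(
    list(term_id = term_id,
         name = name[term_id],
         tree_numbers = tree_numbers[term_id],
         parents = parents, children = children,
         root = root, virtual_root = virtual_root),
    class = "disease_dag")
  validate_dag(dag)
  dag
}

#' Validate a disease DAG
#'
#' Checks acyclicity (via igraph topological sort) and that every term
#' is reachable from the root.
#'
#' @param dag a `disease_dag`.
#' @return The DAG, invisibly; stops on violation.
#' @export
validate_dag <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!dag$root %in% dag$term_id) stop("root not in term set")
  g <- dag_igraph(dag)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::girth(igraph::as_undirected(g))
    stop("graph contains a cycle")
  }
  reach <- igraph::subcomponent(g, dag$root, mode = "out")$name
  miss <- setdiff(dag$term_id, reach)
  if (length(miss))
    stop("terms unreachable from root: ", paste(head(miss, 5L), collapse = ", "))
  invisible(dag)
}

# igraph view of the DAG (directed parent -> child)
dag_igraph <- function(dag) {
  el <- dag_edges(dag)
  igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = dag$term_id, stringsAsFactors = FALSE))
}

#' Edge list of a disease DAG
#'
#' @param dag a `disease_dag`.
#' @return A two-column character matrix (parent, child), rows sorted.
#' @export
dag_edges <- function(dag) {
  ps <- rep(dag$term_id, lengths(dag$children[dag$term_id]))
  cs <- unlist(dag$children[dag$term_id], use.names = FALSE)
  m <- cbind(parent = ps, child = if (is.null(cs)) character(0) else cs)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d terms, %d edges, root '%s'%s\n",
              length(x$term_id), nrow(dag_edges(x)), x$root,
              if (x$virtual_root) " (virtual)" else ""))
  invisible(x)
}

#' Build a disease DAG from a parent-child edge list
#'
#' If exactly one node has no parent it becomes the root; otherwise a
#' single virtual root (IC 0) is attached above all parentless nodes.
#' Duplicate edges are dropped with a warning; cycles are an error.
#'
#' @param edge_list two-column matrix/data.frame of (parent_id,
#'   child_id) character pairs, or a zero-row object.
#' @param nodes optional character vector of node IDs (needed for
#'   isolated nodes, e.g. a single-term DAG with no edges).
#' @param root_id identifier used for the virtual root when one must be
#'   created (default "ROOT"; suffixed if it collides).
#' @return A `disease_dag`.
#' @examples
#' toy <- build_dag_from_edges(cbind(c("R","R","A","A","B"),
#'                                   c("A","B","C","D","E")))
#' toy$root
#' @export
build_dag_from_edges <- function(edge_list, nodes = NULL, root_id = "ROOT") {
  el <- as.matrix(edge_list)
  if (length(el)) storage.mode(el) <- "character"
  if (nrow(el) > 0L && ncol(el) < 2L) stop("edge list needs 2 columns")
  el <- el[, 1:2, drop = FALSE]
  if (nrow(el) > 0L) {
    key <- paste(el[, 1L], el[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)), " duplicate edge(s) removed")
      el <- el[!duplicated(key), , drop = FALSE]
    }
  }
  ids <- sort(unique(c(as.vector(el), nodes)))
  if (!length(ids)) stop("empty node set")
  parentless <- setdiff(ids, el[, 2L])
  if (!length(parentless)) stop("cycle detected: no parentless node exists")
  if (length(parentless) == 1L) {
    root <- parentless
    virtual <- FALSE
  } else {
    root <- root_id
    while (root %in% ids) root <- paste0(root, "_")
    el <- rbind(el, cbind(root, parentless))
    ids <- c(root, ids)
    virtual <- TRUE
  }
  tryCatch(
    new_disease_dag(ids, setNames(ids, ids),
                    setNames(rep(list(character(0)), length(ids)), ids),
                    el, root, virtual),
    error = function(e) {
      if (grepl("cycle", conditionMessage(e)))
        stop("cycle detected involving: ",
             paste(head(find_cycle_nodes(el), 6L), collapse = " -> "))
      stop(e)
    })
}

# name a few nodes on some cycle, for the error message
find_cycle_nodes <- function(el) {
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1L]
  igraph::V(g)$name[comp$membership == big]
}

#' Read a DAG from an edge-list file
#'
#' Two-column TSV (parent_id, child_id); `#` comment lines allowed.
#'
#' @param path file path.
#' @inheritParams build_dag_from_edges
#' @return A `disease_dag`.
#' @export
read_dag_edges <- function(path, root_id = "ROOT") {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, header = FALSE,
                    colClasses = "character")
  build_dag_from_edges(tab, root_id = root_id)
}

#' Export a DAG as node and edge tables
#'
#' Writes `<prefix>_nodes.tsv` (term_id, name, ic) and
#' `<prefix>_edges.tsv` (parent, child).
#'
#' @param dag a `disease_dag`.
#' @param prefix output path prefix.
#' @param ic optional `ic_table`; when given, IC values join the node
#'   table.
#' @return Invisibly, the two paths written.
#' @export
write_dag <- function(dag, prefix, ic = NULL) {
  nodes <- data.frame(term_id = dag$term_id,
                      name = unname(dag$name[dag$term_id]),
                      stringsAsFactors = FALSE)
  if (!is.null(ic)) nodes$ic <- unname(ic$ic[nodes$term_id])
  np <- paste0(prefix, "_nodes.tsv"); ep <- paste0(prefix, "_edges.tsv")
  write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# parent\tchild", ep)
  write.table(as.data.frame(dag_edges(dag)), ep, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE,
              append = TRUE)
  invisible(c(nodes = np, edges = ep))
}

#' Ancestors of a term
#'
#' All terms with a directed path to `term_id`.  With
#' `inclusive = TRUE` (the default) the query term is counted among its
#' own ancestors, so an ancestor/descendant pair has the ancestor as its
#' most informative common ancestor and a leaf compared with itself
#' reaches similarity 1.
#'
#' @param dag a `disease_dag`.
#' @param term_id a term in the DAG.
#' @param inclusive include the term itself?
#' @return Character vector of term IDs (sorted).
#' @export
dag_ancestors <- function(dag, term_id, inclusive = TRUE) {
  check_terms(dag, term_id)
  seen <- character(0)
  frontier <- dag$parents[[term_id]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
  }
  sort(unique(if (inclusive) c(term_id, seen) else seen))
}

#' Descendants of a term
#'
#' @inheritParams dag_ancestors
#' @return Character vector of term IDs (sorted).
#' @export
dag_descendants <- function(dag, term_id, inclusive = TRUE) {
  check_terms(dag, term_id)
  seen <- character(0)
  frontier <- dag$children[[term_id]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(dag$children[frontier], use.names = FALSE))
  }
  sort(unique(if (inclusive) c(term_id, seen) else seen))
}

#' Leaf descendants of a term
#'
#' Leaves (out-degree 0) of the sub-DAG below a term; a leaf returns
#' itself.
#'
#' @inheritParams dag_ancestors
#' @return Character vector of leaf term IDs (sorted).
#' @export
leaves_under <- function(dag, term_id) {
  desc <- dag_descendants(dag, term_id, inclusive = TRUE)
  desc[lengths(dag$children[desc]) == 0L]
}

check_terms <- function(dag, ids) {
  miss <- setdiff(ids, dag$term_id)
  if (length(miss))
    stop("unknown term(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Per-term information content
#'
#' IC(t) = -log p(t) in nats.  The structural method (default) takes
#' p(t) as the inclusive-descendant count of t over the number of terms
#' (excluding any virtual root), which is self-contained: no external
#' annotation corpus is needed.  The annotation method takes p(t) as
#' the add-one-smoothed fraction of associations annotated to t or any
#' descendant.  Both give IC(root) = 0 and IC non-decreasing along every
#' root-to-leaf edge (descendant sets nest).
#'
#' @param dag a `disease_dag`.
#' @param method "structural" or "annotation".
#' @param associations an association table (see [read_associations()])
#'   whose `disease` column holds resolved term IDs; required for the
#'   annotation method.
#' @return An `ic_table`: list with named numeric vectors `ic` and `p`
#'   over all terms, and the `method` used.
#' @examples
#' toy <- build_dag_from_edges(cbind(c("R","R","A","A","B"),
#'                                   c("A","B","C","D","E")))
#' compute_ic(toy)$ic
#' @export
compute_ic <- function(dag, method = c("structural", "annotation"),
                       associations = NULL) {
  method <- match.arg(method)
  ids <- dag$term_id
  if (!length(ids)) stop("empty DAG")
  real <- if (dag$virtual_root) setdiff(ids, dag$root) else ids
  # inclusive descendant sets via reverse topological sweep
  ord <- topo_order(dag)
  desc <- setNames(vector("list", length(ids)), ids)
  for (id in rev(ord)) {
    kids <- dag$children[[id]]
    desc[[id]] <- unique(c(id, unlist(desc[kids], use.names = FALSE)))
  }
  if (method == "structural") {
    cnt <- vapply(desc, function(d) length(intersect(d, real)), 0L)
    p <- pmin(cnt / length(real), 1)
    p[dag$root] <- 1
  } else {
    if (is.null(associations)) stop("annotation method needs associations")
    ann <- table(factor(associations$disease, levels = ids))
    total <- sum(ann)
    if (total == 0L) stop("no associations map to DAG terms")
    cnt <- vapply(desc, function(d) sum(ann[d]), 0)
    p <- (cnt + 1) / (total + 1)
    p[dag$root] <- 1
  }
  structure(list(ic = -log(p), p = p, method = method), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("ic_table (%s): %d terms, IC range [%.4g, %.4g] nats\n",
              x$method, length(x$ic), min(x$ic), max(x$ic)))
  invisible(x)
}

# topological order, parents before children
topo_order <- function(dag) {
  g <- dag_igraph(dag)
  igraph::topo_sort(g, mode = "out")$name
}
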