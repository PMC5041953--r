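#' IC-based distance between two terms
#'
#' The absolute difference of the information contents of the two terms,
#' the metric on which both the most informative common ancestor and
#' the most informative leaf are picked.
#'
#' @param ic an `ic_table` from [compute_ic()].
#' @param a,b term IDs present in the table.
#' @return Non-negative real (nats); zero iff the terms share an IC.
#' @export
ic_distance <- function(ic, a, b) {
  v <- ic$ic[c(a, b)]
  if (anyNA(v)) stop("unknown term(s): ",
                     paste(c(a, b)[is.na(v)], collapse = ", "))
  abs(v[[1]] - v[[2]])
}

#' Most informative common ancestor (MICA)
#'
#' Among the common ancestors of `a` and `b` (each term counted among
#' its own ancestors), returns the term of maximum IC — equivalently the
#' common ancestor closest in IC-distance to the query pair's shared
#' specialization and farthest from the root.  The root is always a
#' common ancestor, so the result is total.  Ties break to the
#' lexicographically smallest term ID for reproducibility.
#'
#' @param dag a `disease_dag`.
#' @param ic an `ic_table`.
#' @param a,b term IDs.
#' @return A term ID.
#' @export
find_mica <- function(dag, ic, a, b) {
  common <- intersect(dag_ancestors(dag, a, inclusive = TRUE),
                      dag_ancestors(dag, b, inclusive = TRUE))
  pick_max_ic(ic$ic, common)
}

#' Most informative leaf (MIL)
#'
#' The maximum-IC leaf descending from a term; a leaf is its own MIL
#' (distance 0).  Ties break lexicographically.
#'
#' @inheritParams find_mica
#' @param a a term ID.
#' @return A term ID.
#' @export
find_mil <- function(dag, ic, a) {
  pick_max_ic(ic$ic, leaves_under(dag, a))
}

# max-IC element, lexicographic tie-break (candidates are sorted IDs)
pick_max_ic <- function(icv, candidates) {
  candidates <- sort(candidates)
  v <- icv[candidates]
  candidates[which.max(v)]
}

#' Similarity components of a disease term pair
#'
#' Decomposes a pair into the three edge-based components: `alpha`, the
#' IC of the MICA (its IC-distance from the root); `beta`, the mean
#' IC-distance of each query term to its own most informative leaf (how
#' general the two terms are); and `gamma`, the summed distance from the
#' MICA to each query term.  Distances are IC-based by default; set
#' `dist_method = "edges"` to use shortest-path edge counts instead (a
#' sensitivity-analysis variant, off by default).
#'
#' @inheritParams find_mica
#' @param dist_method "ic" (default) or "edges" for `gamma`/`beta`.
#' @return A list of class `semsim_components`: `mica`, `mil_a`,
#'   `mil_b`, `alpha`, `beta`, `gamma`.
#' @export
semantic_components <- function(dag, ic, a, b,
                                dist_method = c("ic", "edges")) {
  dist_method <- match.arg(dist_method)
  mica <- find_mica(dag, ic, a, b)
  mil_a <- find_mil(dag, ic, a)
  mil_b <- find_mil(dag, ic, b)
  dfun <- if (dist_method == "ic") {
    function(x, y) ic_distance(ic, x, y)
  } else {
    g <- dag_igraph(dag)
    function(x, y) {
      as.numeric(igraph::distances(g, x, y,
                                   mode = "all", weights = NA))
    }
  }
  structure(list(
    mica = mica, mil_a = mil_a, mil_b = mil_b,
    alpha = unname(ic$ic[mica]),
    beta = (dfun(a, mil_a) + dfun(b, mil_b)) / 2,
    gamma = dfun(mica, a) + dfun(mica, b)),
    class = "semsim_components")
}

#' Edge-based semantic similarity of two disease terms
#'
#' SS = alpha/(alpha + beta) * 1/(1 + gamma), in \[0, 1\].  SS = 1 for a
#' leaf compared with itself (beta = gamma = 0); SS = 0 whenever the
#' only common ancestor is the root (alpha = 0), including the
#' degenerate alpha = beta = 0 case, reflecting that terms meeting only
#' at the root share no commonality.
#'
#' @inheritParams semantic_components
#' @return Real in \[0, 1\]; symmetric in (a, b).
#' @examples
#' toy <- build_dag_from_edges(cbind(c("R","R","A","A","B"),
#'                                   c("A","B","C","D","E")))
#' ic <- compute_ic(toy)
#' semantic_similarity(toy, ic, "C", "D")
#' @export
semantic_similarity <- function(dag, ic, a, b,
                                dist_method = c("ic", "edges")) {
  comp <- semantic_components(dag, ic, a, b, dist_method)
  ss_from_components(comp$alpha, comp$beta, comp$gamma)
}

ss_from_components <- function(alpha, beta, gamma) {
  if (alpha == 0) return(0)
  alpha / (alpha + beta) * 1 / (1 + gamma)
}

#' Disease-disease semantic similarity matrix
#'
#' Pairwise edge-based similarity over a term subset (default: all
#' terms except a virtual root).  The diagonal uses the same formula:
#' 1 for leaves, alpha/(alpha + beta) for internal terms.  Ancestor
#' sets, MILs and IC are precomputed once, so the matrix scales to a
#' few thousand terms.
#'
#' @inheritParams semantic_components
#' @param terms character vector of term IDs (default all non-virtual
#'   terms).
#' @return Symmetric numeric matrix with `terms` as dimnames.
#' @export
semantic_similarity_matrix <- function(dag, ic, terms = NULL,
                                       dist_method = c("ic", "edges")) {
  dist_method <- match.arg(dist_method)
  if (is.null(terms)) {
    terms <- dag$term_id
    if (dag$virtual_root) terms <- setdiff(terms, dag$root)
  }
  check_terms(dag, terms)
  terms <- sort(unique(terms))
  n <- length(terms)
  icv <- ic$ic
  ord <- topo_order(dag)
  # inclusive ancestor sets as integer indices into ord
  pos <- setNames(seq_along(ord), ord)
  anc <- setNames(vector("list", length(ord)), ord)
  for (id in ord) {
    ps <- dag$parents[[id]]
    anc[[id]] <- sort(unique(c(pos[[id]],
                               unlist(anc[ps], use.names = FALSE))))
  }
  # MIL per term via reverse sweep: best (max IC, lex) leaf below
  mil <- setNames(character(length(ord)), ord)
  for (id in rev(ord)) {
    kids <- dag$children[[id]]
    if (!length(kids)) { mil[id] <- id; next }
    cand <- sort(unique(unname(mil[kids])))
    mil[id] <- cand[which.max(icv[cand])]
  }
  edge_dist <- NULL
  if (dist_method == "edges") {
    g <- dag_igraph(dag)
    edge_dist <- igraph::distances(g, mode = "all", weights = NA)
  }
  ssm <- matrix(0, n, n, dimnames = list(terms, terms))
  beta_half <- setNames(numeric(n), terms)  # per-term distance to own MIL
  for (t in terms) {
    beta_half[t] <- if (dist_method == "ic") abs(icv[t] - icv[mil[t]])
                    else edge_dist[t, mil[t]]
  }
  for (i in seq_len(n)) {
    a <- terms[i]
    for (j in i:n) {
      b <- terms[j]
      common_idx <- intersect(anc[[a]], anc[[b]])
      common <- ord[common_idx]
      # lexicographic tie-break among max-IC common ancestors
      mx <- max(icv[common])
      mica <- min(common[icv[common] == mx])
      alpha <- unname(icv[mica])
      if (alpha == 0) { ssm[i, j] <- ssm[j, i] <- 0; next }
      beta <- (beta_half[a] + beta_half[b]) / 2
      gamma <- if (dist_method == "ic")
        abs(icv[mica] - icv[a]) + abs(icv[mica] - icv[b])
      else edge_dist[mica, a] + edge_dist[mica, b]
      ssm[i, j] <- ssm[j, i] <- alpha / (alpha + beta) / (1 + gamma)
    }
  }
  ssm
}

#' Write a similarity matrix as TSV
#'
#' Wide format: header row/column of IDs.  `long = TRUE` writes the
#' 3-column long format (id_a, id_b, value) over the upper triangle
#' including the diagonal.
#'
#' @param m symmetric matrix with dimnames.
#' @param path output file.
#' @param long write long format instead of wide.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path, long = FALSE) {
  if (long) {
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id_a = rownames(m)[idx[, 1]],
                     id_b = colnames(m)[idx[, 2]],
                     value = m[idx], stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#'
#' Auto-detects wide vs long format from the header.
#'
#' @param path file path.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (identical(hdr[1:3], c("id_a", "id_b", "value"))) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    ids <- sort(unique(c(df$id_a, df$id_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(df$id_a, df$id_b)] <- df$value
    m[cbind(df$id_b, df$id_a)] <- df$value
    m
  } else {
    m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                              row.names = 1L, check.names = FALSE))
    storage.mode(m) <- "double"
    m
  }
}
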