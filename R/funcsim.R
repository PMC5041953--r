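#' Best match of a disease against a disease group
#'
#' The maximum semantic similarity between one disease and any member
#' of a group — the per-disease contribution to the group similarity.
#'
#' @param ss symmetric disease similarity matrix with term IDs as
#'   dimnames.
#' @param disease a term ID.
#' @param group non-empty character vector of term IDs.
#' @return Real in \[0, 1\].
#' @export
best_match <- function(ss, disease, group) {
  if (!length(group)) stop("empty disease group")
  miss <- setdiff(c(disease, group), rownames(ss))
  if (length(miss)) stop("unknown disease(s): ", paste(miss, collapse = ", "))
  max(ss[disease, group])
}

#' Directed similarity of one disease group to another
#'
#' Sum over the first group of each disease's best match in the second;
#' not symmetric in general.
#'
#' @inheritParams best_match
#' @param group_i,group_j non-empty character vectors of term IDs.
#' @return Non-negative real (at most `length(group_i)`).
#' @export
group_similarity <- function(ss, group_i, group_j) {
  if (!length(group_i) || !length(group_j)) stop("empty disease group")
  sum(vapply(group_i, best_match, 0, ss = ss, group = group_j))
}

#' Functional similarity of two lncRNAs from their disease groups
#'
#' The two directed group similarities, normalized by the total group
#' size: FS = (S_i->j + S_j->i) / (|G(i)| + |G(j)|).  Symmetric and in
#' \[0, 1\] because every best match is.  Note the self-similarity
#' FS(i, i) equals the mean diagonal similarity of the group's diseases,
#' which is 1 only when every associated disease is a leaf.
#'
#' @inheritParams group_similarity
#' @param on_empty "error" (default) or "zero": curated tables can lose
#'   all diseases during ontology mapping; pipelines may prefer FS = 0
#'   with a warning over a hard stop.
#' @return Real in \[0, 1\].
#' @export
functional_similarity <- function(ss, group_i, group_j,
                                  on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  if (!length(group_i) || !length(group_j)) {
    if (on_empty == "zero") {
      warning("empty disease group; returning FS = 0")
      return(0)
    }
    stop("empty disease group")
  }
  group_i <- unique(group_i); group_j <- unique(group_j)
  (group_similarity(ss, group_i, group_j) +
     group_similarity(ss, group_j, group_i)) /
    (length(group_i) + length(group_j))
}

#' lncRNA-lncRNA functional similarity matrix
#'
#' Pairwise functional similarity over all lncRNAs of an association
#' table whose diseases resolve in the similarity matrix.  lncRNAs with
#' no resolvable disease are dropped and reported via the `dropped`
#' attribute.  The raw diagonal is kept by default (it is below 1 when
#' a group contains non-leaf diseases); `unit_diagonal = TRUE`
#' overwrites it with 1 for predictors that expect a unit diagonal.
#'
#' @inheritParams best_match
#' @param associations association table (data.frame with `lncrna` and
#'   `disease` columns, diseases as resolved term IDs), or a named list
#'   of disease groups.
#' @param unit_diagonal force the diagonal to 1?
#' @return Symmetric numeric matrix, lncRNA IDs as dimnames; attribute
#'   `dropped` lists lncRNAs removed for having no mapped disease.
#' @examples
#' toy <- build_dag_from_edges(cbind(c("R","R","A","A","B"),
#'                                   c("A","B","C","D","E")))
#' ss <- semantic_similarity_matrix(toy, compute_ic(toy))
#' assoc <- data.frame(lncrna = c("l1","l2","l3"),
#'                     disease = c("C","D","E"))
#' functional_similarity_matrix(ss, assoc)
#' @export
functional_similarity_matrix <- function(ss, associations,
                                         unit_diagonal = FALSE) {
  groups <- if (is.data.frame(associations)) {
    split(as.character(associations$disease),
          as.character(associations$lncrna))
  } else associations
  groups <- lapply(groups, function(g) unique(intersect(g, rownames(ss))))
  dropped <- names(groups)[lengths(groups) == 0L]
  groups <- groups[lengths(groups) > 0L]
  ids <- sort(names(groups))
  n <- length(ids)
  fs <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    fs[i, j] <- fs[j, i] <-
      functional_similarity(ss, groups[[ids[i]]], groups[[ids[j]]])
  }
  if (unit_diagonal) diag(fs) <- 1
  if (length(dropped))
    message(length(dropped), " lncRNA(s) dropped (no mapped disease): ",
            paste(dropped, collapse = ", "))
  attr(fs, "dropped") <- dropped
  fs
}
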