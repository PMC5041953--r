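#' Read an lncRNA-disease association table
#'
#' Plain-text TSV or CSV, one association per row: first column the
#' lncRNA symbol, second the disease name or ID, optional third an
#' evidence string (column positions overridable).  The delimiter and a
#' header line are auto-detected.  Identifiers are trimmed and
#' case-folded for identity (the first-seen spelling is kept for
#' display) and exact duplicate pairs are removed, with the number of
#' removed duplicates reported via the `duplicates_removed` attribute.
#'
#' @param path file path (or connection).
#' @param sep field separator; NULL (default) auto-detects "\\t" vs ",".
#' @param lncrna_col,disease_col,evidence_col column positions.
#' @return data.frame of class `association_table` with columns
#'   `lncrna`, `disease` and (optionally) `evidence`; attributes
#'   `duplicates_removed` and `display` (case-fold -> first-seen
#'   spelling map).
#' @export
read_associations <- function(path, sep = NULL, lncrna_col = 1L,
                              disease_col = 2L, evidence_col = 3L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty association file")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  tab <- read.table(text = lines, sep = sep, header = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    colClasses = "character", fill = TRUE)
  if (ncol(tab) < 2L) stop("association table needs at least 2 columns")
  # header heuristic: first row made of obvious column names
  header_words <- c("lncrna", "lncrna_id", "lncrna_symbol", "rna",
                    "disease", "disease_name", "disease_id", "term",
                    "term_id", "name", "evidence", "pmid", "source")
  if (nrow(tab) > 1L &&
      any(tolower(unlist(tab[1, ])) %in% header_words))
    tab <- tab[-1L, , drop = FALSE]
  rec <- data.frame(
    lncrna = trimws(tab[[lncrna_col]]),
    disease = trimws(tab[[disease_col]]),
    stringsAsFactors = FALSE)
  if (ncol(tab) >= evidence_col)
    rec$evidence <- trimws(tab[[evidence_col]])
  rec <- rec[nzchar(rec$lncrna) & nzchar(rec$disease), , drop = FALSE]
  if (!nrow(rec)) stop("no associations after filtering")
  normalize_associations(rec)
}

# fold case for identity, keep first-seen spelling, dedup pairs
normalize_associations <- function(rec) {
  fold_l <- tolower(rec$lncrna); fold_d <- tolower(rec$disease)
  disp <- c(setNames(rec$lncrna, fold_l)[!duplicated(fold_l)],
            setNames(rec$disease, fold_d)[!duplicated(fold_d)])
  rec$lncrna <- unname(disp[fold_l])
  rec$disease <- unname(disp[fold_d])
  key <- paste(fold_l, fold_d, sep = "\r")
  ndup <- sum(duplicated(key))
  rec <- rec[!duplicated(key), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, duplicates_removed = ndup, display = disp,
            class = c("association_table", "data.frame"))
}

#' Resolve association disease references against a DAG
#'
#' Matches each disease reference to a DAG term by exact
#' case-insensitive comparison with the term ID or name; no fuzzy
#' matching.  Unmatched records are removed and returned in the
#' `unmapped` attribute rather than raising an error.  Records that
#' resolve to the same (lncRNA, term) pair through different spellings
#' are deduplicated.
#'
#' @param table an `association_table`.
#' @param dag a `disease_dag`.
#' @return The mapped `association_table` (diseases replaced by term
#'   IDs) with attribute `unmapped` (data.frame of dropped records).
#' @export
map_to_dag <- function(table, dag) {
  lut <- c(setNames(dag$term_id, tolower(dag$term_id)),
           setNames(dag$term_id, tolower(unname(dag$name))))
  hit <- lut[tolower(table$disease)]
  unmapped <- table[is.na(hit), , drop = FALSE]
  mapped <- table[!is.na(hit), , drop = FALSE]
  mapped$disease <- unname(hit[!is.na(hit)])
  if (!nrow(mapped)) stop("no associations map to DAG terms")
  out <- normalize_associations(mapped)
  attr(out, "unmapped") <- unmapped
  out
}

#' Binary lncRNA x disease adjacency matrix
#'
#' Rows are lncRNAs, columns diseases, both in sorted order for
#' deterministic layout; entry 1 iff the association is present.
#'
#' @param table a mapped `association_table`.
#' @return Binary integer matrix with dimnames.
#' @export
association_matrix <- function(table) {
  ln <- sort(unique(table$lncrna))
  di <- sort(unique(table$disease))
  m <- matrix(0L, length(ln), length(di), dimnames = list(ln, di))
  m[cbind(table$lncrna, table$disease)] <- 1L
  m
}

#' Write an association table as TSV
#'
#' @param table an `association_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_associations <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an adjacency matrix with explicit label headers
#'
#' @param m binary matrix from [association_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}
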