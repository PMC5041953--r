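#' Parse MeSH descriptors into a disease DAG
#'
#' Reads the standard MeSH descriptor distribution in either the ASCII
#' record dialect (records separated by `*NEWRECORD`, fields `MH = `,
#' `UI = `, `MN = `) or the XML descriptor dialect
#' (`DescriptorRecord`/`DescriptorUI`/`TreeNumber`); the dialect is
#' auto-detected from the first non-blank character.  Only descriptors
#' with at least one tree number under `category_prefix` are kept
#' (default "C", the disease category).  An edge p -> c is drawn
#' whenever some tree number of c equals a tree number of p plus one
#' dot-separated segment, so a descriptor sitting in several branches
#' gets several parents.  A single virtual root is attached above the
#' top-level category nodes.
#'
#' @param path path to a MeSH descriptor file (ASCII `.bin` or XML).
#' @param category_prefix tree-number prefix selecting branches; a bare
#'   category letter ("C") selects the whole category, a deeper prefix
#'   ("C04") selects that subtree.
#' @return A `disease_dag` whose terms carry MeSH UIs as `term_id`,
#'   headings as `name` and the selected tree numbers.
#' @export
parse_mesh_descriptors <- function(path, category_prefix = "C") {
  txt <- readLines(path, warn = FALSE)
  first <- sub("^\\s*", "", paste(txt[nzchar(trimws(txt))][1], collapse = ""))
  recs <- if (startsWith(first, "<")) {
    parse_mesh_xml(path)
  } else {
    parse_mesh_ascii(txt)
  }
  mesh_records_to_dag(recs, category_prefix)
}

# ASCII dialect: *NEWRECORD separators, "FIELD = value" lines
parse_mesh_ascii <- function(lines) {
  idx <- which(trimws(lines) == "*NEWRECORD")
  if (!length(idx)) stop("no *NEWRECORD separators found")
  bounds <- c(idx, length(lines) + 1L)
  recs <- vector("list", length(idx))
  for (r in seq_along(idx)) {
    block <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    get <- function(field) {
      pat <- paste0("^", field, " = ")
      sub(pat, "", block[grepl(pat, block)])
    }
    ui <- get("UI"); mh <- get("MH"); mn <- get("MN")
    if (length(ui) != 1L || length(mh) != 1L)
      stop("malformed record ", r, ": missing or repeated UI/MH")
    recs[[r]] <- list(ui = ui, mh = mh, mn = mn)
  }
  recs
}

parse_mesh_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  if (!length(nodes)) stop("no DescriptorRecord elements found")
  lapply(seq_along(nodes), function(r) {
    n <- nodes[[r]]
    ui <- xml2::xml_text(xml2::xml_find_first(n, "./DescriptorUI"))
    mh <- xml2::xml_text(xml2::xml_find_first(n, "./DescriptorName/String"))
    mn <- xml2::xml_text(xml2::xml_find_all(n, ".//TreeNumberList/TreeNumber"))
    if (is.na(ui) || !nzchar(ui) || is.na(mh) || !nzchar(mh))
      stop("malformed record ", r, ": missing UI/MH")
    list(ui = ui, mh = mh, mn = mn)
  })
}

# does tree number tn fall under prefix? a bare letter matches its whole
# category; otherwise whole leading dot-separated segments must match
tree_under_prefix <- function(tn, prefix) {
  if (grepl("^[A-Z]$", prefix)) return(startsWith(tn, prefix))
  tn == prefix | startsWith(tn, paste0(prefix, "."))
}

mesh_records_to_dag <- function(recs, category_prefix) {
  keep <- lapply(recs, function(r) {
    tn <- r$mn[tree_under_prefix(r$mn, category_prefix)]
    if (length(tn)) list(ui = r$ui, mh = r$mh, mn = sort(tn)) else NULL
  })
  keep <- Filter(Negate(is.null), keep)
  if (!length(keep)) stop("no descriptors under prefix '", category_prefix, "'")
  uis <- vapply(keep, `[[`, "", "ui")
  if (anyDuplicated(uis)) stop("duplicate descriptor UI: ",
                               uis[duplicated(uis)][1])
  ord <- order(uis)
  keep <- keep[ord]; uis <- uis[ord]
  tn2ui <- list()
  for (r in keep) for (tn in r$mn) tn2ui[[tn]] <- r$ui
  edges <- matrix(character(0), 0, 2)
  tops <- character(0)
  for (r in keep) {
    got_parent <- FALSE
    for (tn in r$mn) {
      if (grepl(".", tn, fixed = TRUE)) {
        par_tn <- sub("\\.[^.]+$", "", tn)
        pui <- tn2ui[[par_tn]]
        if (!is.null(pui) && pui != r$ui) {
          edges <- rbind(edges, c(pui, r$ui))
          got_parent <- TRUE
        }
      }
    }
    if (!got_parent) tops <- c(tops, r$ui)
  }
  root <- "MESH_ROOT"
  while (root %in% uis) root <- paste0(root, "_")
  edges <- unique(rbind(edges, cbind(root, unique(tops))))
  nm <- setNames(c("virtual root", vapply(keep, `[[`, "", "mh")), c(root, uis))
  tns <- c(setNames(list(character(0)), root),
           setNames(lapply(keep, `[[`, "mn"), uis))
  dag <- tryCatch(
    new_disease_dag(c(root, uis), nm, tns, edges, root, virtual_root = TRUE),
    error = function(e) {
      if (grepl("cycle", conditionMessage(e)))
        stop("corrupt input: tree numbers induce a cycle")
      stop(e)
    })
  dag
}
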