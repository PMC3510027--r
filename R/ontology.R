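#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, alt_id, is_obsolete)
#' into a DAG. Obsolete terms are dropped; alternate ids map to their
#' canonical term. The result is validated: edges must point to known
#' terms, the graph must be acyclic, and every namespace must have a root
#' (a term with no is_a parent).
#'
#' @param path OBO 1.2 file.
#' @return object of class `gene_ontology`: `terms` (data.table id, name,
#'   namespace), `parents` / `children` (named lists of character vectors),
#'   `roots` (named by namespace), `alt` (named vector alt_id -> id).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    field <- sub(":.*$", "", chunk)
    value <- trimws(sub("^[^:]+: ?", "", chunk))
    get1 <- function(f) if (any(field == f)) value[field == f][1] else NA_character_
    terms[[i]] <- list(
      id = get1("id"), name = get1("name"), namespace = get1("namespace"),
      obsolete = identical(get1("is_obsolete"), "true"),
      # is_a lines may carry a trailing "! name" comment
      is_a = sub("\\s*!.*$", "", value[field == "is_a"]),
      alt_id = value[field == "alt_id"])
  }
  terms <- Filter(function(t) !is.na(t$id) && !t$obsolete, terms)
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term id ", ids[duplicated(ids)][1], " in ", path)
  }
  tab <- data.table::data.table(
    id = ids,
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"))
  tab$namespace[is.na(tab$namespace)] <- "default"
  parents <- lapply(terms, function(t) t$is_a[t$is_a %in% ids])
  names(parents) <- ids
  dangling <- unlist(lapply(terms, function(t) setdiff(t$is_a, ids)))
  if (length(dangling)) {
    stop("is_a reference to unknown or obsolete term ", dangling[1],
         " in ", path)
  }
  alt <- unlist(lapply(terms, function(t) {
    stats::setNames(rep(t$id, length(t$alt_id)), t$alt_id)
  }))
  if (is.null(alt)) alt <- character(0)
  build_ontology(tab, parents, alt)
}

# Assembles and validates the gene_ontology structure from a term table and
# a parent list (child id -> parent ids).
#' @keywords internal
build_ontology <- function(terms, parents, alt = character(0)) {
  ids <- terms$id
  children <- vector("list", length(ids))
  names(children) <- ids
  for (child in ids) {
    for (p in parents[[child]]) children[[p]] <- c(children[[p]], child)
  }
  # Kahn's algorithm over is_a edges; leftovers imply a cycle.
  indeg <- lengths(parents)
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg_w <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg_w[ch] <- indeg_w[ch] - 1L
      if (indeg_w[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    stuck <- ids[indeg_w > 0L]
    # walk parent pointers inside the stuck set until a repeat closes a cycle
    path <- stuck[1]
    repeat {
      nxt <- intersect(parents[[path[length(path)]]], stuck)[1]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt)[1]:length(path)], nxt)
        stop("cycle in is_a edges: ", paste(cyc, collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  roots <- ids[lengths(parents) == 0L]
  ns_roots <- split(roots, terms$namespace[match(roots, ids)])
  missing_ns <- setdiff(unique(terms$namespace), names(ns_roots))
  if (length(missing_ns)) {
    stop("namespace ", missing_ns[1], " has no root term")
  }
  structure(list(terms = terms, parents = parents, children = children,
                 roots = ns_roots, alt = alt),
            class = "gene_ontology")
}

#' @export
print.gene_ontology <- function(x, ...) {
  cat("Gene ontology DAG: ", nrow(x$terms), " terms, ",
      sum(lengths(x$parents)), " is_a edges, namespaces: ",
      paste(names(x$roots), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Resolve a (possibly alternate) term id to its canonical id
#' @param dag a `gene_ontology`.
#' @param id character vector of term or alt ids.
#' @return canonical ids (NA where unknown).
#' @export
resolve_term <- function(dag, id) {
  out <- ifelse(id %in% dag$terms$id, id, unname(dag$alt[id]))
  out
}

#' Parse a GAF 2.x annotation file
#'
#' Reads gene -> GO term annotations: column 2 is the gene id, column 4 the
#' qualifier, column 5 the term id. Rows whose qualifier contains `NOT` are
#' excluded (they assert the gene does not have the function). Comment
#' lines (`!`) are skipped.
#'
#' @param path GAF 2.x tab-separated file.
#' @return object of class `annotation_set`: `direct` (named list gene ->
#'   character vector of term ids) and `propagated` (NULL until
#'   [propagate()] is applied).
#' @export
parse_gaf <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 15L)) {
    bad <- which(keep)[which(nf < 15L)[1]]
    stop("malformed GAF row (", nf[nf < 15L][1], " columns) at line ",
         bad, " of ", path)
  }
  gene <- vapply(rows, `[[`, character(1), 2L)
  qual <- vapply(rows, `[[`, character(1), 4L)
  term <- vapply(rows, `[[`, character(1), 5L)
  not <- grepl("(^|\\|)NOT($|\\|)", qual)
  direct <- lapply(split(term[!not], gene[!not]), unique)
  structure(list(direct = direct, propagated = NULL),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set: ", length(x$direct), " genes, ",
      sum(lengths(x$direct)), " direct annotations",
      if (!is.null(x$propagated)) ", propagated" else "", "\n", sep = "")
  invisible(x)
}

#' Ancestor sets for every term (inclusive)
#'
#' @param dag a `gene_ontology`.
#' @return named list: term id -> character vector of the term and all its
#'   is_a ancestors.
#' @export
term_ancestors <- function(dag) {
  ids <- dag$terms$id
  lev <- term_levels(dag, longest = TRUE) # parents strictly shallower
  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (id in ids[order(lev[ids])]) {
    anc[[id]] <- unique(c(id, unlist(anc[dag$parents[[id]]], use.names = FALSE)))
  }
  anc
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; DAG-aware enrichment requires counting over these closed
#' sets. Annotations to unknown terms (after alt-id resolution) are skipped
#' with a warning.
#'
#' @param dag a `gene_ontology`.
#' @param annots an `annotation_set` (from [parse_gaf()] or built directly).
#' @return the `annotation_set` with `propagated` filled: gene -> ancestor-
#'   closed term set.
#' @export
propagate <- function(dag, annots) {
  anc <- term_ancestors(dag)
  annots$propagated <- lapply(annots$direct, function(terms) {
    terms <- resolve_term(dag, terms)
    unknown <- is.na(terms)
    if (any(unknown)) {
      warning("skipping annotation(s) to unknown term(s)", call. = FALSE)
      terms <- terms[!unknown]
    }
    unique(unlist(anc[terms], use.names = FALSE))
  })
  annots
}

#' Term levels: is_a path length from the namespace root
#'
#' The level of a term is the shortest is_a distance from its namespace
#' root (root = 0); near-root levels are uninformative and filtered in
#' enrichment. `longest = TRUE` gives the longest-path variant used
#' internally for topological ordering.
#'
#' @param dag a `gene_ontology`.
#' @param longest use longest instead of shortest root distance.
#' @return named integer vector over all term ids.
#' @export
term_levels <- function(dag, longest = FALSE) {
  ids <- dag$terms$id
  lev <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  pick <- if (longest) max else min
  frontier <- unlist(dag$roots, use.names = FALSE)
  lev[frontier] <- 0L
  # relax repeatedly: bounded by DAG depth
  repeat {
    changed <- FALSE
    nxt <- character(0)
    for (v in frontier) {
      for (ch in dag$children[[v]]) {
        cand <- lev[v] + 1L
        if (is.na(lev[ch]) || pick(lev[ch], cand) != lev[ch]) {
          lev[ch] <- if (is.na(lev[ch])) cand else pick(lev[ch], cand)
          nxt <- c(nxt, ch)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    frontier <- unique(nxt)
  }
  lev
}

#' Level of a single term
#' @param dag a `gene_ontology`.
#' @param term canonical term id.
#' @return integer level (root = 0).
#' @export
term_level <- function(dag, term) {
  lev <- term_levels(dag)
  if (!term %in% names(lev)) stop("unknown term ", term)
  l <- lev[[term]]
  if (is.na(l)) stop("term ", term, " is unreachable from any root")
  l
}
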