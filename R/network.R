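#' Read an interactome edge list (SIF or 3-column TSV)
#'
#' Lines are `node relation node`, whitespace-separated (SIF) or
#' tab-separated. Relations must be `direct` (physical contact; SIF `pp`
#' is accepted as a synonym) or `indirect` (functional). Edges are
#' undirected and deduplicated; self-loops are dropped with a warning.
#'
#' @param path SIF/TSV file.
#' @return object of class `interactome`: `nodes` (character) and `edges`
#'   (data.table from, to, relation with from < to).
#' @export
read_interactome <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(rows)
  if (any(nf != 3L)) {
    stop("expected 3 fields per interactome row; line ", which(nf != 3L)[1],
         " has ", nf[nf != 3L][1])
  }
  a <- vapply(rows, `[[`, character(1), 1L)
  rel <- vapply(rows, `[[`, character(1), 2L)
  b <- vapply(rows, `[[`, character(1), 3L)
  rel[rel == "pp"] <- "direct"
  bad <- setdiff(unique(rel), c("direct", "indirect"))
  if (length(bad)) stop("unknown relation kind: ", bad[1])
  loop <- a == b
  if (any(loop)) {
    warning("dropping ", sum(loop), " self-loop row(s)", call. = FALSE)
    a <- a[!loop]; b <- b[!loop]; rel <- rel[!loop]
  }
  edges <- data.table::data.table(from = pmin(a, b), to = pmax(a, b),
                                  relation = rel)
  edges <- unique(edges, by = c("from", "to", "relation"))
  data.table::setorder(edges, from, to, relation)
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges[]),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("Interactome: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$relation == "direct"), " direct)\n", sep = "")
  invisible(x)
}

#' @keywords internal
as_igraph <- function(g, direct_only = FALSE) {
  edges <- g$edges
  if (direct_only) edges <- edges[edges$relation == "direct", ]
  edges <- unique(edges[, c("from", "to")])
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

#' @keywords internal
new_hit_network <- function(members, edges) {
  deg <- stats::setNames(integer(nrow(members)), members$node)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  members$degree <- unname(deg[members$node])
  data.table::setorder(members, node)
  data.table::setorder(edges, from, to)
  structure(list(members = members[], edges = edges[]),
            class = "hit_network")
}

#' @export
print.hit_network <- function(x, ...) {
  cat("Hit network: ", nrow(x$members), " nodes (",
      sum(x$members$flag == "seed"), " seeds, ",
      sum(x$members$flag == "connector"), " connectors), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Direct-connection subnetwork of hit genes
#'
#' A hit gene enters the network only if it connects directly (no
#' intervening nodes) to another hit: the induced subgraph on the seeds,
#' with isolated seeds removed.
#'
#' @param g an `interactome`.
#' @param seeds hit gene ids (present or absent from the interactome;
#'   absent seeds simply cannot connect).
#' @param direct_only traverse only `direct` (physical) edges.
#' @return object of class `hit_network`: `members` (node, flag, degree)
#'   and `edges` (from, to), degrees counted within the network.
#' @export
direct_subnetwork <- function(g, seeds, direct_only = FALSE) {
  if (!length(seeds)) stop("seeds must be nonempty")
  seeds <- unique(seeds)
  edges <- g$edges
  if (direct_only) edges <- edges[edges$relation == "direct", ]
  keep <- edges$from %in% seeds & edges$to %in% seeds
  edges <- unique(edges[keep, c("from", "to")])
  members <- data.table::data.table(
    node = sort(unique(c(edges$from, edges$to))), flag = "seed")
  new_hit_network(members, edges)
}

#' Add a focus node and its connections to an existing network
#'
#' Adds one gene of interest (e.g. the disease gene the screen was built
#' around) to a hit network, wiring every interactome edge between it and
#' current members. The node is flagged `focus` even if no edge lands.
#'
#' @param net a `hit_network`.
#' @param g the `interactome` providing the edges.
#' @param focus_id gene id to add; must exist in the interactome.
#' @return the augmented `hit_network`.
#' @export
add_focus_node <- function(net, g, focus_id) {
  if (!focus_id %in% g$nodes) {
    stop("focus node ", focus_id, " absent from interactome")
  }
  members <- net$members[, c("node", "flag")]
  if (!focus_id %in% members$node) {
    members <- rbind(members,
                     data.table::data.table(node = focus_id, flag = "focus"))
  } else {
    members$flag[members$node == focus_id] <- "focus"
  }
  inc <- g$edges$from == focus_id | g$edges$to == focus_id
  other <- ifelse(g$edges$from == focus_id, g$edges$to, g$edges$from)
  new_edges <- g$edges[inc & other %in% net$members$node, c("from", "to")]
  edges <- unique(rbind(net$edges[, c("from", "to")],
                        data.table::data.table(from = pmin(new_edges$from,
                                                           new_edges$to),
                                               to = pmax(new_edges$from,
                                                         new_edges$to))))
  new_hit_network(members, edges)
}

#' Shortest-path-augmented hit network
#'
#' Connects hits through intervening interactome nodes: for every seed pair
#' whose shortest path in the interactome contains at most
#' `max_intervening` non-seed interior nodes, one canonical shortest path
#' is kept (among qualifying equal-length paths, the one whose interior
#' node-id sequence is lexicographically smallest, making the result
#' deterministic and independent of input row order). The network is the
#' union of kept paths; interior non-seed nodes are flagged `connector`,
#' seeds with no kept path `isolated`.
#'
#' @param g an `interactome`.
#' @param seeds hit gene ids.
#' @param max_intervening maximum non-seed interior nodes per path
#'   (default 1).
#' @param direct_only traverse only `direct` edges.
#' @return a `hit_network`; members flagged seed/connector/isolated.
#' @export
shortest_path_network <- function(g, seeds, max_intervening = 1L,
                                  direct_only = FALSE) {
  if (max_intervening < 0L) stop("max_intervening must be >= 0")
  seeds <- unique(seeds)
  present <- intersect(seeds, g$nodes)
  ig <- as_igraph(g, direct_only)
  kept_edges <- list()
  kept_nodes <- character(0)
  if (length(present) >= 2L) {
    ord <- sort(present)
    for (i in seq_len(length(ord) - 1L)) {
      paths <- igraph::all_shortest_paths(ig, from = ord[i],
                                          to = ord[(i + 1L):length(ord)],
                                          mode = "all")$vpaths
      if (!length(paths)) next
      paths <- lapply(paths, function(v) igraph::as_ids(v))
      ends <- vapply(paths, function(p) p[length(p)], character(1))
      for (target in unique(ends)) {
        cand <- paths[ends == target]
        interiors <- lapply(cand, function(p) p[-c(1L, length(p))])
        n_nonseed <- vapply(interiors, function(int) {
          sum(!int %in% present)
        }, integer(1))
        # canonical path: fewest non-seed interiors, then lexicographically
        # smallest interior sequence — independent of max_intervening, so
        # raising the cap only ever adds members
        keys <- vapply(interiors, paste, character(1), collapse = "\r")
        best_i <- order(n_nonseed, keys)[1]
        if (n_nonseed[best_i] > max_intervening) next
        best <- cand[[best_i]]
        kept_nodes <- c(kept_nodes, best)
        if (length(best) > 1L) {
          kept_edges[[length(kept_edges) + 1L]] <- data.table::data.table(
            from = pmin(best[-length(best)], best[-1L]),
            to = pmax(best[-length(best)], best[-1L]))
        }
      }
    }
  }
  edges <- if (length(kept_edges)) {
    unique(data.table::rbindlist(kept_edges))
  } else {
    data.table::data.table(from = character(0), to = character(0))
  }
  connected <- unique(kept_nodes)
  members <- data.table::data.table(
    node = unique(c(present, connected)))
  members$flag <- ifelse(!members$node %in% present, "connector",
                         ifelse(members$node %in% connected, "seed",
                                "isolated"))
  new_hit_network(members, edges)
}

#' Degree report for a hit network
#'
#' @param net a `hit_network`.
#' @return data.table (node, flag, degree) sorted by descending degree,
#'   ties broken lexicographically by node id.
#' @export
degree_report <- function(net) {
  rep <- data.table::copy(net$members)
  rep <- rep[order(-rep$degree, rep$node)]
  rep[]
}

#' Write a hit network as GraphML
#' @param net a `hit_network`.
#' @param path destination `.graphml` file.
#' @export
write_network_graphml <- function(net, path) {
  ig <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = as.data.frame(net$members))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a hit network as DOT
#' @param net a `hit_network`.
#' @param path destination `.dot` file.
#' @export
write_network_dot <- function(net, path) {
  shape <- c(seed = "ellipse", connector = "box", isolated = "ellipse",
             focus = "doubleoctagon")
  lines <- c("graph hit_network {", "  node [style=filled];")
  for (i in seq_len(nrow(net$members))) {
    m <- net$members[i]
    lines <- c(lines, sprintf(
      "  \"%s\" [shape=%s, fillcolor=\"%s\"];", m$node, shape[[m$flag]],
      if (m$flag == "connector") "lightgrey" else "lightblue"))
  }
  for (i in seq_len(nrow(net$edges))) {
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\";",
                              net$edges$from[i], net$edges$to[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
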