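# Independent reference computations used to cross-check the package.
# Deliberately written as plain loops / closed forms, not via the package's
# own code paths.

# Normal-equations OLS slope: (n Sxy - Sx Sy) / (n Sxx - Sx^2)
oracle_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Sort-and-cummin Benjamini-Hochberg reference
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  scaled <- p[o] * n / (n:1)
  adj <- pmin(1, cummin(scaled))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Position normalization by explicit loops over a long table
oracle_position_normalize <- function(df) {
  out <- df$value
  for (i in seq_len(nrow(df))) {
    same_pos <- df$well == df$well[i]
    out[i] <- df$value[i] / mean(df$value[same_pos])
  }
  out
}

# True-path closure by repeated edge relaxation until a fixed point
oracle_closure <- function(parents, terms) {
  out <- unique(terms)
  repeat {
    grown <- unique(c(out, unlist(parents[out], use.names = FALSE)))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

# Exhaustive hypergeometric upper tail: enumerate every k_draw-subset of the
# urn and count those containing >= k_obs white genes.
oracle_hyper_tail <- function(urn, white, k_draw, k_obs) {
  if (k_draw == 0L) return(if (k_obs <= 0L) 1 else 0)
  subsets <- utils::combn(urn, k_draw)
  hits <- colSums(matrix(subsets %in% white, nrow = k_draw))
  mean(hits >= k_obs)
}

# Small random ontology + annotations for property sweeps: term 1 is the
# root; each later term picks 1-2 parents among earlier terms.
random_tiny_ontology <- function(n_terms, n_genes, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[ids[1]]] <- character(0)
  for (i in seq_len(n_terms)[-1]) {
    pool <- ids[seq_len(i - 1L)]
    parents[[ids[i]]] <- sample(pool, min(length(pool), sample(1:2, 1)))
  }
  genes <- sprintf("g%02d", seq_len(n_genes))
  direct <- lapply(stats::setNames(genes, genes), function(g) {
    sample(ids[-1], sample(1:3, 1))
  })
  study <- sample(genes, max(2L, rbinom(1, n_genes, 0.4)))
  list(ids = ids, parents = parents, genes = genes, direct = direct,
       study = study)
}

# Build a gene_ontology / annotation_set pair from explicit parent lists,
# bypassing the OBO/GAF parsers (single default namespace).
make_dag <- function(parents, namespace = "biological_process") {
  ids <- names(parents)
  obo <- c("format-version: 1.2", "")
  for (id in ids) {
    obo <- c(obo, "[Term]", paste0("id: ", id),
             paste0("name: name of ", id),
             paste0("namespace: ", namespace),
             if (length(parents[[id]])) paste0("is_a: ", parents[[id]]),
             "")
  }
  path <- tempfile(fileext = ".obo")
  writeLines(obo, path)
  parse_obo(path)
}

make_annots <- function(direct) {
  structure(list(direct = lapply(direct, unique), propagated = NULL),
            class = "annotation_set")
}

# Brute-force all-pairs BFS distances over an undirected edge list
oracle_bfs_dist <- function(nodes, edges, from) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Minimum number of non-seed interior nodes over all shortest a-b paths,
# by dynamic programming along the BFS layer structure (Inf if unreachable)
oracle_min_nonseed <- function(nodes, edges, a, b, seeds) {
  da <- oracle_bfs_dist(nodes, edges, a)
  db <- oracle_bfs_dist(nodes, edges, b)
  d <- da[b]
  if (!is.finite(d)) return(Inf)
  on_path <- nodes[is.finite(da[nodes]) & is.finite(db[nodes]) &
                     da[nodes] + db[nodes] == d]
  f <- stats::setNames(rep(Inf, length(on_path)), on_path)
  f[a] <- 0
  if (d >= 1) {
    for (i in seq_len(d)) {
      layer <- on_path[da[on_path] == i]
      prev <- on_path[da[on_path] == i - 1]
      for (v in layer) {
        nb <- intersect(prev, c(edges$to[edges$from == v],
                                edges$from[edges$to == v]))
        if (!length(nb)) next
        cost <- if (v == b) 0 else as.numeric(!v %in% seeds)
        f[v] <- min(f[nb]) + cost
      }
    }
  }
  f[b]
}

# Random undirected interactome table for network oracles
random_graph_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- sample(nodes, n_edges, replace = TRUE)
  keep <- from != to
  edges <- unique(data.frame(from = pmin(from[keep], to[keep]),
                             to = pmax(from[keep], to[keep]),
                             stringsAsFactors = FALSE))
  list(nodes = nodes, edges = edges)
}

write_sif <- function(edges, path, relation = "direct") {
  writeLines(paste(edges$from, relation, edges$to), path)
}

# Small in-memory screen tables for normalization tests
make_batch <- function(values, plate_ids = NULL) {
  # values: matrix plates x wells, dimnames well labels
  if (is.null(plate_ids)) plate_ids <- sprintf("P%02d", seq_len(nrow(values)))
  data.table::data.table(
    plate_id = rep(plate_ids, each = ncol(values)),
    well = rep(colnames(values), nrow(values)),
    activity = as.vector(t(values)))
}
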