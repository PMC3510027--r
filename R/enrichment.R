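# Index propagated annotations as term -> genes, restricted to a universe.
#' @keywords internal
term_gene_index <- function(annots, universe) {
  if (is.null(annots$propagated)) {
    stop("annotations must be propagated first (see propagate())")
  }
  prop <- annots$propagated[names(annots$propagated) %in% universe]
  gene <- rep(names(prop), lengths(prop))
  term <- unlist(prop, use.names = FALSE)
  lapply(split(gene, term), unique)
}

#' Parent-Child-Union enrichment p-value for one term
#'
#' Term-for-term enrichment tests inherit signal from enriched ancestors
#' because annotations obey the true-path rule. The Parent-Child-Union
#' variant conditions on the union of the term's parents instead: given the
#' number of study genes annotated to the parent union, how surprising is
#' the number also annotated to the term? The p-value is the hypergeometric
#' upper tail with the parent-union population as the urn. For a root term
#' the parent union is the whole population and the test reduces to the
#' classic term-for-term test.
#'
#' @param dag a `gene_ontology`.
#' @param annots a propagated `annotation_set`.
#' @param study,population character vectors of gene ids, study inside
#'   population.
#' @param term canonical term id.
#' @param index optional precomputed `term_gene_index(annots, population)`
#'   (avoids re-indexing when testing many terms).
#' @return list: `p` (upper-tail probability), counts `k_term` / `k_parents`
#'   (study genes in term / in parent union) and `m_term` / `m_parents`
#'   (population genes in term / in parent union), and `degenerate` (TRUE
#'   when no study gene is annotated to the parent union; then p = 1 by
#'   convention).
#' @export
parent_child_union_p <- function(dag, annots, study, population, term,
                                 index = NULL) {
  if (!all(study %in% population)) stop("study genes must be in population")
  if (is.null(index)) index <- term_gene_index(annots, population)
  parents <- dag$parents[[term]]
  if (is.null(dag$parents[[term]]) && !term %in% dag$terms$id) {
    stop("unknown term ", term)
  }
  pu <- if (length(parents)) {
    unique(unlist(index[parents], use.names = FALSE))
  } else {
    population
  }
  term_genes <- index[[term]]
  m_parents <- length(pu)
  m_term <- length(intersect(term_genes, pu))
  k_parents <- length(intersect(study, pu))
  k_term <- length(intersect(study, term_genes))
  if (k_parents == 0L) {
    return(list(p = 1, k_term = k_term, k_parents = k_parents,
                m_term = m_term, m_parents = m_parents, degenerate = TRUE))
  }
  p <- stats::phyper(k_term - 1L, m_term, m_parents - m_term, k_parents,
                     lower.tail = FALSE)
  list(p = p, k_term = k_term, k_parents = k_parents, m_term = m_term,
       m_parents = m_parents, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; input order is
#' preserved in the output.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-proportion pooled z-test (enrichment QC filter)
#'
#' Compares a category's proportion in the hit set against its proportion
#' in the screened library. With sample proportions p1 = x1/n1 and
#' p2 = x2/n2 and pooled proportion p = (x1+x2)/(n1+n2), the statistic is
#'
#'   z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))
#'
#' referred to the standard normal, two-tailed. Categories whose hit-set
#' proportion is not significantly different from the library's are
#' filtered out of enrichment results. When the pooled proportion is 0 or 1
#' the statistic is undefined; p = 1 is returned with `degenerate = TRUE`.
#' Results with p1 < p2 (hit set under-represented) are flagged `depleted`.
#'
#' @param x1,n1 category count and total in the study (hit) set.
#' @param x2,n2 category count and total in the comparison (library) set.
#' @return list of class `proportions_test`: `p_hat1`, `p_hat2`,
#'   `p_hat_pooled`, `z`, `p_two_tailed`, `degenerate`, `depleted`.
#' @export
proportions_qc <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    out <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p_hat1 = p1,
                p_hat2 = p2, p_hat_pooled = pooled, z = NA_real_,
                p_two_tailed = 1, degenerate = TRUE, depleted = p1 < p2)
    return(structure(out, class = "proportions_test"))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p_hat1 = p1,
                 p_hat2 = p2, p_hat_pooled = pooled, z = z,
                 p_two_tailed = 2 * stats::pnorm(-abs(z)),
                 degenerate = FALSE, depleted = p1 < p2),
            class = "proportions_test")
}

#' @export
print.proportions_test <- function(x, ...) {
  cat("Two-proportion z-test: ", x$x1, "/", x$n1, " vs ", x$x2, "/", x$n2,
      "\n  z = ", format(x$z, digits = 4), ", two-tailed p = ",
      format(x$p_two_tailed, digits = 4),
      if (x$depleted) " (depleted)" else "", "\n", sep = "")
  invisible(x)
}

#' Parent-Child-Union GO enrichment of a study set
#'
#' Tests every term carrying at least one (propagated) study gene with the
#' Parent-Child-Union hypergeometric test, adjusts across exactly the
#' tested terms with Benjamini-Hochberg, and filters: adjusted p must be at
#' or below `alpha`, the term level (shortest is_a distance from its
#' namespace root) must exceed `min_level` (near-root categories are
#' uninformative), and — when a library gene list is supplied — the
#' category's hit-set proportion must differ from its library proportion at
#' `qc_alpha` in the two-proportion QC test. The population should be the
#' genome-scale background; the screened library enters only through the QC
#' filter.
#'
#' @param dag a `gene_ontology`.
#' @param annots an `annotation_set` (propagated automatically if needed).
#' @param study hit gene ids (subset of `population`).
#' @param population background gene ids.
#' @param library_genes screened-library gene ids for the QC filter, or
#'   NULL to skip it.
#' @param alpha threshold on BH-adjusted p (default 0.05).
#' @param min_level terms at level `min_level` or shallower are excluded
#'   (default 2, i.e. levels 0-2 dropped).
#' @param qc_alpha threshold on the QC test's raw two-tailed p (default
#'   0.05).
#' @param exclude_terms optional term ids to drop regardless of statistics
#'   (manual curation, e.g. categories inapplicable to the organism).
#' @return data.table with one row per tested term: term, name, namespace,
#'   level, study_count, study_size, pop_count, pop_size, p_raw, p_adj,
#'   qc_z, qc_p, qc_depleted, kept; sorted by p_adj then p_raw. The `kept`
#'   rows are the reportable enriched categories.
#' @export
enrich <- function(dag, annots, study, population, library_genes = NULL,
                   alpha = 0.05, min_level = 2L, qc_alpha = 0.05,
                   exclude_terms = NULL) {
  study <- unique(study)
  population <- unique(population)
  if (!length(study)) stop("empty study set")
  if (!all(study %in% population)) {
    stop("study genes missing from population: ",
         paste(utils::head(setdiff(study, population), 3), collapse = ", "))
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(annots$propagated)) annots <- propagate(dag, annots)
  index <- term_gene_index(annots, population)
  study_count <- vapply(index, function(g) length(intersect(g, study)),
                        integer(1))
  tested <- names(index)[study_count > 0L]
  if (!length(tested)) stop("no term is annotated to any study gene")
  pcu <- lapply(tested, function(t) {
    parent_child_union_p(dag, annots, study, population, t, index = index)
  })
  lev <- term_levels(dag)
  res <- data.table::data.table(
    term = tested,
    name = dag$terms$name[match(tested, dag$terms$id)],
    namespace = dag$terms$namespace[match(tested, dag$terms$id)],
    level = lev[tested],
    study_count = study_count[tested],
    study_size = length(study),
    pop_count = vapply(index[tested], length, integer(1)),
    pop_size = length(population),
    p_raw = vapply(pcu, `[[`, numeric(1), "p"))
  res$p_adj <- bh_adjust(res$p_raw)
  if (!is.null(library_genes)) {
    library_genes <- unique(library_genes)
    lib_index <- term_gene_index(annots, library_genes)
    qc <- lapply(tested, function(t) {
      proportions_qc(study_count[[t]], length(study),
                     length(lib_index[[t]]), length(library_genes))
    })
    res$qc_z <- vapply(qc, `[[`, numeric(1), "z")
    res$qc_p <- vapply(qc, `[[`, numeric(1), "p_two_tailed")
    res$qc_depleted <- vapply(qc, `[[`, logical(1), "depleted")
    qc_pass <- res$qc_p <= qc_alpha
  } else {
    res$qc_z <- NA_real_
    res$qc_p <- NA_real_
    res$qc_depleted <- NA
    qc_pass <- TRUE
  }
  res$kept <- res$p_adj <= alpha & res$level > min_level & qc_pass
  if (!is.null(exclude_terms)) {
    res$kept <- res$kept & !res$term %in% exclude_terms
  }
  data.table::setorder(res, p_adj, p_raw, term)
  res[]
}

#' Export enriched terms and their ancestry as a DOT graph
#'
#' Writes a Graphviz DOT file containing the kept (enriched) terms plus all
#' their is_a ancestors, the induced is_a edges, one fill color family per
#' namespace with intensity scaled by -log10 of the adjusted p-value.
#'
#' @param results output of [enrich()] (rows with `kept == TRUE` are drawn
#'   highlighted).
#' @param dag a `gene_ontology`.
#' @param path destination `.dot` file.
#' @return `path`, invisibly.
#' @export
export_dag_graph <- function(results, dag, path) {
  kept <- results[results$kept == TRUE, ]
  anc <- term_ancestors(dag)
  nodes <- sort(unique(unlist(anc[kept$term], use.names = FALSE)))
  hues <- c(biological_process = "0.60", cellular_component = "0.35",
            molecular_function = "0.15")
  lines <- c("digraph enriched_go {", "  rankdir=BT;",
             "  node [shape=box, style=filled];")
  if (length(nodes)) {
    logp <- -log10(pmax(kept$p_adj, 1e-300))
    sat <- stats::setNames(pmin(1, logp / max(logp, 1)), kept$term)
    for (n in nodes) {
      ns <- dag$terms$namespace[match(n, dag$terms$id)]
      hue <- if (!is.na(ns) && ns %in% names(hues)) hues[[ns]] else "0.0"
      s <- if (n %in% kept$term) 0.15 + 0.65 * sat[[n]] else 0
      nm <- dag$terms$name[match(n, dag$terms$id)]
      lines <- c(lines, sprintf(
        "  \"%s\" [label=\"%s\\n%s\", fillcolor=\"%s %.3f 1.0\"];",
        n, n, nm, hue, s))
    }
    for (n in nodes) {
      for (p in intersect(dag$parents[[n]], nodes)) {
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", n, p))
      }
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
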