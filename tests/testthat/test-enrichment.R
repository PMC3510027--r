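test_that("parent-child-union p-value matches exhaustive enumeration on a toy DAG", {
  # parent union holds g1..g10, the term g1..g5; study = the term's genes
  dag <- make_dag(list(root = character(0), parent = "root",
                       term = "parent"))
  genes <- sprintf("g%02d", 1:12)
  direct <- c(
    lapply(stats::setNames(genes[1:5], genes[1:5]), function(g) "term"),
    lapply(stats::setNames(genes[6:10], genes[6:10]), function(g) "parent"),
    lapply(stats::setNames(genes[11:12], genes[11:12]), function(g) "root"))
  annots <- propagate(dag, make_annots(direct))
  study <- genes[1:5]
  res <- parent_child_union_p(dag, annots, study, genes, "term")
  expect_equal(res$m_parents, 10L)
  expect_equal(res$m_term, 5L)
  expect_equal(res$k_parents, 5L)
  expect_equal(res$k_term, 5L)
  ref <- oracle_hyper_tail(genes[1:10], genes[1:5], 5L, 5L)
  expect_equal(res$p, ref, tolerance = 1e-12)
})

test_that("parent-child-union degenerate conventions hold", {
  dag <- make_dag(list(root = character(0), parent = "root",
                       term = "parent"))
  # term's genes saturate the parent union: conditioning leaves no signal
  direct <- list(g1 = "term", g2 = "term", g3 = "root")
  annots <- propagate(dag, make_annots(direct))
  res <- parent_child_union_p(dag, annots, c("g1", "g2"),
                              c("g1", "g2", "g3"), "term")
  expect_equal(res$p, 1)

  # study disjoint from the term: upper tail at count 0 is 1
  res0 <- parent_child_union_p(dag, annots, "g3", c("g1", "g2", "g3"),
                               "term")
  expect_equal(res0$p, 1)
  expect_true(res0$degenerate) # no study gene in the parent union
})

test_that("parent-child-union equals enumeration across random tiny ontologies", {
  for (seed in 1:50) {
    tiny <- random_tiny_ontology(sample(4:12, 1), sample(6:15, 1),
                                 seed = 1000 + seed)
    dag <- make_dag(tiny$parents)
    annots <- propagate(dag, make_annots(tiny$direct))
    index <- lapply(
      stats::setNames(tiny$ids, tiny$ids),
      function(t) {
        names(Filter(function(terms) {
          t %in% oracle_closure(tiny$parents, terms)
        }, tiny$direct))
      })
    term <- sample(tiny$ids[-1], 1)
    res <- parent_child_union_p(dag, annots, tiny$study, tiny$genes, term)
    pu <- sort(unique(unlist(index[tiny$parents[[term]]])))
    k_draw <- length(intersect(tiny$study, pu))
    k_obs <- length(intersect(tiny$study, index[[term]]))
    ref <- if (k_draw == 0L) 1 else {
      oracle_hyper_tail(pu, intersect(index[[term]], pu), k_draw, k_obs)
    }
    expect_equal(res$p, ref, tolerance = 1e-9,
                 label = paste("seed", seed, "term", term))
  }
})

test_that("BH adjustment matches the sort-and-cummin reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(55)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "must lie in")
  expect_error(bh_adjust(c(-0.1)), "must lie in")
})

test_that("BH adjustment is monotone in the input p-values", {
  set.seed(66)
  p <- runif(200)
  adj <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("two-proportion QC test matches the pooled formula", {
  eq <- proportions_qc(10, 100, 100, 1000)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_tailed, 1)

  # long-hand computation of the pooled z for the screen-shaped counts
  x1 <- 13; n1 <- 130; x2 <- 150; n2 <- 7494
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  z_hand <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  res <- proportions_qc(x1, n1, x2, n2)
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p_two_tailed, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  # cross-check against the chi-squared equivalence (z^2 = X^2)
  pt <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(res$p_two_tailed, pt$p.value, tolerance = 1e-9)

  deg <- proportions_qc(0, 130, 0, 7494)
  expect_true(deg$degenerate)
  expect_equal(deg$p_two_tailed, 1)
})

test_that("QC z statistic is antisymmetric under swapping the samples", {
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(10:200, 1); n2 <- sample(10:5000, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    a <- proportions_qc(x1, n1, x2, n2)
    b <- proportions_qc(x2, n2, x1, n1)
    if (a$degenerate) {
      expect_true(b$degenerate)
    } else {
      expect_equal(a$z, -b$z, tolerance = 1e-12)
      expect_equal(a$p_two_tailed, b$p_two_tailed, tolerance = 1e-12)
    }
  }
})

test_that("enrichment recovers a planted term and applies all filters", {
  ont <- generate_ontology(tempfile("enr"), n_planted = 1L, fold = 10,
                           seed = 41L)
  dag <- parse_obo(ont$paths$obo)
  annots <- propagate(dag, parse_gaf(ont$paths$gaf))
  study <- readLines(ont$paths$study)
  population <- readLines(ont$paths$population)
  res <- enrich(dag, annots, study, population,
                library_genes = readLines(ont$paths$library))
  expect_true(all(ont$truth$planted %in% res$term[res$kept]))
  expect_true(all(res$level[res$kept] > 2L))
  expect_true(all(res$p_adj[res$kept] <= 0.05))
  expect_true(all(res$qc_p[res$kept] <= 0.05))
  expect_true(all(res$p_adj >= res$p_raw))

  # the level filter excludes shallow terms no matter how small their p
  shallow <- res[res$level <= 2L & res$p_adj <= 0.05, ]
  if (nrow(shallow)) expect_false(any(shallow$kept))

  # manual exclusion list removes a kept term
  excl <- res$term[res$kept][1]
  res2 <- enrich(dag, annots, study, population,
                 library_genes = readLines(ont$paths$library),
                 exclude_terms = excl)
  expect_false(res2$kept[res2$term == excl])

  expect_error(enrich(dag, annots, character(0), population), "empty study")
  expect_error(enrich(dag, annots, c(study, "MISSING"), population),
               "missing from population")
})

test_that("per-term type-I error of the PCU test is controlled at the null", {
  ont <- generate_ontology(tempfile("t1e"), n_planted = 0L, seed = 53L)
  dag <- parse_obo(ont$paths$obo)
  annots <- propagate(dag, parse_gaf(ont$paths$gaf))
  population <- readLines(ont$paths$population)
  index <- screensift:::term_gene_index(annots, population)
  terms <- names(index)[vapply(index, length, integer(1)) >= 20]
  terms <- setdiff(terms, dag$roots$biological_process)[1:10]
  set.seed(60)
  n_draw <- 400L
  reject <- matrix(NA, n_draw, length(terms))
  for (d in seq_len(n_draw)) {
    study <- sample(population, 130L)
    for (j in seq_along(terms)) {
      reject[d, j] <- parent_child_union_p(
        dag, annots, study, population, terms[j], index = index)$p <= 0.05
    }
  }
  rate <- colMeans(reject)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_draw)
  expect_true(all(rate <= bound))
})

test_that("DOT export contains enriched terms and their root paths", {
  dag <- make_dag(list(root = character(0), mid = "root", leaf = "mid"))
  res <- data.table::data.table(
    term = "leaf", name = "name of leaf",
    namespace = "biological_process", level = 2L, p_adj = 0.001,
    kept = TRUE)
  path <- tempfile(fileext = ".dot")
  export_dag_graph(res, dag, path)
  dot <- readLines(path)
  expect_true(any(grepl("\"leaf\"", dot)))
  expect_true(any(grepl("\"mid\" -> \"root\"", dot, fixed = TRUE)))

  empty <- res[res$kept == FALSE, ]
  export_dag_graph(empty, dag, path)
  dot <- readLines(path)
  expect_equal(dot[1], "digraph enriched_go {")
  expect_false(any(grepl("->", dot, fixed = TRUE)))
})
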