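test_that("interactome parsing deduplicates, keeps relations, drops loops", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B direct A", "B indirect C", "C indirect B",
               "D direct D"), path)
  expect_warning(g <- read_interactome(path), "self-loop")
  expect_equal(g$nodes, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$edges$relation, c("direct", "indirect"))

  bad <- tempfile(fileext = ".sif")
  writeLines("A knows B", bad)
  expect_error(read_interactome(bad), "unknown relation kind: knows")
})

test_that("generated interactomes parse back to the written edge multiset", {
  net <- generate_interactome(tempfile("gi"), seed = 19L)
  g <- read_interactome(net$paths$sif)
  raw <- read.table(net$paths$sif,
                    col.names = c("from", "relation", "to"),
                    stringsAsFactors = FALSE)
  ref <- unique(data.frame(from = pmin(raw$from, raw$to),
                           to = pmax(raw$from, raw$to),
                           relation = raw$relation))
  expect_equal(nrow(g$edges), nrow(ref))
})

test_that("direct subnetwork is the induced seed subgraph minus isolates", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A direct B", "B direct C", "A direct C",
               "D direct X", "X direct E"), path)
  g <- read_interactome(path)
  net <- direct_subnetwork(g, c("A", "B", "C", "D", "E"))
  expect_equal(net$members$node, c("A", "B", "C"))
  expect_true(all(net$members$degree == 2L))

  # brute-force double-loop oracle on random graphs
  for (seed in 1:10) {
    rg <- random_graph_edges(60, 150, seed)
    sif <- tempfile(fileext = ".sif")
    write_sif(rg$edges, sif)
    gg <- read_interactome(sif)
    set.seed(seed)
    seeds <- sample(rg$nodes, 25)
    net <- direct_subnetwork(gg, seeds)
    keep <- character(0)
    for (a in seeds) for (b in seeds) {
      if (a < b && any((rg$edges$from == a & rg$edges$to == b) |
                       (rg$edges$from == b & rg$edges$to == a))) {
        keep <- union(keep, c(a, b))
      }
    }
    expect_setequal(net$members$node, keep)
  }
})

test_that("direct subnetwork is idempotent", {
  rg <- random_graph_edges(50, 120, 101)
  sif <- tempfile(fileext = ".sif")
  write_sif(rg$edges, sif)
  g <- read_interactome(sif)
  set.seed(101)
  net <- direct_subnetwork(g, sample(rg$nodes, 20))
  if (nrow(net$members)) {
    again <- direct_subnetwork(g, net$members$node)
    expect_equal(again$members, net$members)
    expect_equal(again$edges, net$edges)
  }
})

test_that("focus node joins with exactly its edges to current members", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A direct B", "F direct A", "F direct B", "F direct X",
               "G direct X"), path)
  g <- read_interactome(path)
  net <- direct_subnetwork(g, c("A", "B"))
  with_f <- add_focus_node(net, g, "F")
  expect_equal(with_f$members$flag[with_f$members$node == "F"], "focus")
  expect_equal(with_f$members$degree[with_f$members$node == "F"], 2L)

  isolated <- add_focus_node(net, g, "G")
  expect_equal(isolated$members$degree[isolated$members$node == "G"], 0L)
  expect_error(add_focus_node(net, g, "NOPE"), "absent from interactome")
})

test_that("shortest-path network adds connectors within the cap", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A direct B", "B direct C", "P direct Q"), path)
  g <- read_interactome(path)
  net <- shortest_path_network(g, c("A", "C"), max_intervening = 1L)
  expect_setequal(net$members$node, c("A", "B", "C"))
  expect_equal(net$members$flag[net$members$node == "B"], "connector")

  # seeds in separate components stay isolated
  apart <- shortest_path_network(g, c("A", "P"), max_intervening = 2L)
  expect_setequal(apart$members$node, c("A", "P"))
  expect_true(all(apart$members$flag == "isolated"))
})

test_that("shortest-path membership matches a BFS brute-force oracle", {
  for (seed in 1:10) {
    rg <- random_graph_edges(60, 140, 300 + seed)
    sif <- tempfile(fileext = ".sif")
    write_sif(rg$edges, sif)
    g <- read_interactome(sif)
    set.seed(300 + seed)
    seeds <- sort(sample(rg$nodes, 15))
    net <- shortest_path_network(g, seeds, max_intervening = 1L)

    # oracle: a seed pair connects iff some shortest path between them has
    # at most one non-seed interior node (dynamic program over BFS layers)
    connected <- character(0)
    for (a in seeds) {
      for (b in seeds[seeds > a]) {
        if (oracle_min_nonseed(rg$nodes, rg$edges, a, b, seeds) <= 1) {
          connected <- union(connected, c(a, b))
        }
      }
    }
    got_seeds <- net$members$node[net$members$flag == "seed"]
    expect_setequal(got_seeds, connected)

    conns <- net$members$node[net$members$flag == "connector"]
    for (x in conns) {
      dx <- oracle_bfs_dist(rg$nodes, rg$edges, x)
      touching <- seeds[is.finite(dx[seeds]) & dx[seeds] == 1]
      expect_true(length(touching) >= 2)
    }
  }
})

test_that("shortest-path network generalizes the direct subnetwork at cap 0", {
  for (seed in 1:5) {
    rg <- random_graph_edges(50, 120, 500 + seed)
    sif <- tempfile(fileext = ".sif")
    write_sif(rg$edges, sif)
    g <- read_interactome(sif)
    set.seed(500 + seed)
    seeds <- sample(rg$nodes, 20)
    sp0 <- shortest_path_network(g, seeds, max_intervening = 0L)
    direct <- direct_subnetwork(g, seeds)
    expect_setequal(sp0$members$node[sp0$members$flag != "isolated"],
                    direct$members$node)
    expect_equal(sp0$edges, direct$edges)
  }
})

test_that("raising the intervening cap never removes members", {
  rg <- random_graph_edges(60, 130, 901)
  sif <- tempfile(fileext = ".sif")
  write_sif(rg$edges, sif)
  g <- read_interactome(sif)
  set.seed(901)
  seeds <- sample(rg$nodes, 15)
  prev <- character(0)
  for (cap in 0:3) {
    net <- shortest_path_network(g, seeds, max_intervening = cap)
    members <- net$members$node[net$members$flag != "isolated"]
    expect_true(all(prev %in% members))
    prev <- members
  }
})

test_that("network construction is independent of input row order", {
  rg <- random_graph_edges(40, 100, 111)
  set.seed(111)
  seeds <- sample(rg$nodes, 12)
  shuffled <- rg$edges[sample.int(nrow(rg$edges)), ]
  p1 <- tempfile(fileext = ".sif"); p2 <- tempfile(fileext = ".sif")
  write_sif(rg$edges, p1); write_sif(shuffled, p2)
  g1 <- read_interactome(p1); g2 <- read_interactome(p2)
  n1 <- shortest_path_network(g1, seeds)
  n2 <- shortest_path_network(g2, seeds)
  expect_equal(n1$members, n2$members)
  expect_equal(n1$edges, n2$edges)
  d1 <- tempfile(); d2 <- tempfile()
  write_network_dot(n1, d1); write_network_dot(n2, d2)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("degree report sorts by degree then node id", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A direct B", "B direct C", "A direct C",
               "HUB direct A", "HUB direct B", "HUB direct C",
               "HUB direct Z"), path)
  g <- read_interactome(path)
  net <- direct_subnetwork(g, c("A", "B", "C", "HUB", "Z"))
  rep <- degree_report(net)
  expect_equal(rep$node[1], "HUB")
  expect_equal(rep$degree[1], 4L)
  expect_equal(rep$node[2:4], c("A", "B", "C"))
})
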