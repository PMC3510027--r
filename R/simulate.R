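# Run code with a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Fixed control-well positions (column 1 plus the top of column 12), three
# wells per role on a 96-well plate.
#' @keywords internal
default_control_layout <- function(controls_per_role = 3L) {
  roles <- rep(c("neg_control", "pos_control", "tox_control_nt",
                 "tox_control_casp3"), each = controls_per_role)
  n <- length(roles)
  col1 <- paste0(LETTERS[1:8], 1)
  col12 <- paste0(LETTERS[1:8], 12)
  wells <- c(col1, col12)[seq_len(n)]
  stats::setNames(roles, wells)
}

#' Simulate an arrayed siRNA screen with known ground truth
#'
#' Emulates the structure the normalization pipeline is designed for:
#' 96-well plates with 12 fixed-position control wells (3 wells each of 4
#' roles) and 84 test wells; each source plate transfected in `replicates`
#' copies on the same screening day; days holding up to `plates_per_batch`
#' plates. Per-well raw activity is
#' `base_activity * effect * position_factor(well) * plate_scale(plate)`
#' with multiplicative log-normal position and plate factors and Gaussian
#' replicate noise on the effect scale; kinetic reads are linear,
#' `RFU(t) = slope * t + baseline + N(0, rfu_noise_sd)` with
#' `slope = activity * protein_mg`. Null siRNAs have effect 1; `n_spiked`
#' suppressors draw effects uniformly from `effect_range`.
#'
#' @param out_dir directory to write into (created if needed).
#' @param n_sirna number of siRNA pools.
#' @param n_spiked number of spiked suppressors among them.
#' @param effect_range suppressor effect bounds inside (0, 1); default a
#'   point mass at 0.4.
#' @param replicates plates of cells per siRNA source plate (3 or 4 in
#'   screens of this design).
#' @param plates_per_batch maximum plates per screening day (28-30 in the
#'   emulated design; replicate copies always share a day).
#' @param noise_sd SD of the Gaussian replicate noise on the normalized
#'   effect scale.
#' @param position_sdlog,plate_sdlog log-normal SDs of position and plate
#'   factors.
#' @param n_reads,read_interval_min kinetic read schedule (default 8 reads
#'   every 44 min).
#' @param rfu_noise_sd additive Gaussian read noise in RFU.
#' @param base_activity negative-control activity in RFU min^-1 mg^-1.
#' @param protein_mg nominal per-well protein mass in mg (log-normal
#'   variation with SD `protein_sdlog` around it).
#' @param protein_sdlog log-normal SD of protein mass.
#' @param control_effects named effects of the four control roles relative
#'   to negative control.
#' @param controls_per_role control wells per role per plate.
#' @param seed integer RNG seed; output is a pure function of parameters
#'   and seed.
#' @return list: `paths` (kinetics, protein, layout, manifest, gene_map,
#'   truth files) and `truth` (effects, spiked ids, position factors, plate
#'   scales, control positions, parameters).
#' @export
generate_screen <- function(out_dir, n_sirna = 2000L, n_spiked = 0L,
                            effect_range = c(0.4, 0.4), replicates = 3L,
                            plates_per_batch = 30L, noise_sd = 0.05,
                            position_sdlog = 0.10, plate_sdlog = 0.15,
                            n_reads = 8L, read_interval_min = 44,
                            rfu_noise_sd = 1.0, base_activity = 1500,
                            protein_mg = 0.01, protein_sdlog = 0.05,
                            control_effects = c(neg_control = 1,
                                                pos_control = 0.3,
                                                tox_control_nt = 0.15,
                                                tox_control_casp3 = 0.10),
                            controls_per_role = 3L, seed = 1L) {
  if (n_spiked > n_sirna) stop("n_spiked cannot exceed n_sirna")
  if (any(effect_range <= 0) || any(effect_range >= 1)) {
    stop("effect_range must lie inside (0, 1)")
  }
  if (plates_per_batch < replicates) {
    stop("plates_per_batch must allow at least one replicated source plate")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wells <- plate_wells()
  ctrl <- default_control_layout(controls_per_role)
  test_wells <- setdiff(wells, names(ctrl))
  n_source <- ceiling(n_sirna / length(test_wells))
  sirna_ids <- sprintf("siRNA%05d", seq_len(n_sirna))
  gene_ids <- sprintf("G%05d", seq_len(n_sirna))

  with_seed(seed, {
    spiked <- sort(sample.int(n_sirna, n_spiked))
    effects <- rep(1, n_sirna)
    effects[spiked] <- stats::runif(n_spiked, effect_range[1], effect_range[2])
    names(effects) <- sirna_ids
    pos_factor <- stats::setNames(
      stats::rlnorm(length(wells), 0, position_sdlog), wells)

    # source plate -> siRNA assignment (row-major fill of test wells)
    assign_idx <- split(seq_len(n_sirna),
                        ceiling(seq_len(n_sirna) / length(test_wells)))
    src_per_day <- max(1L, plates_per_batch %/% replicates)
    rows <- vector("list", n_source * replicates)
    plate_meta <- vector("list", n_source * replicates)
    plate_scales <- numeric(0)
    k <- 0L
    for (s in seq_len(n_source)) {
      idx <- assign_idx[[s]]
      well_of <- stats::setNames(test_wells[seq_along(idx)], sirna_ids[idx])
      batch_id <- sprintf("D%02d", ceiling(s / src_per_day))
      for (r in seq_len(replicates)) {
        k <- k + 1L
        plate_id <- sprintf("P%03d_r%d", s, r)
        scale <- stats::rlnorm(1, 0, plate_sdlog)
        plate_scales[plate_id] <- scale
        role <- ifelse(wells %in% names(ctrl), ctrl[wells], "test")
        sirna <- rep(NA_character_, length(wells))
        used <- wells %in% well_of
        sirna[used] <- names(well_of)[match(wells[used], well_of)]
        # unfilled test wells on the last plate become mock wells (effect
        # 1, empty siRNA id) so every plate shares the same geometry
        eff <- ifelse(role == "test",
                      ifelse(is.na(sirna), 1, effects[sirna]),
                      control_effects[role])
        noisy_eff <- eff + stats::rnorm(length(wells), 0, noise_sd)
        activity <- base_activity * noisy_eff * pos_factor[wells] * scale
        prot <- protein_mg * stats::rlnorm(length(wells), 0, protein_sdlog)
        rows[[k]] <- data.table::data.table(
          plate_id = plate_id, well = wells, role = role,
          sirna_id = ifelse(is.na(sirna), "", sirna),
          activity = activity, protein_mg = prot)
        plate_meta[[k]] <- data.table::data.table(
          plate_id = plate_id, batch_id = batch_id, replicate_index = r)
      }
    }
    grid <- data.table::rbindlist(rows)
    manifest <- data.table::rbindlist(plate_meta)

    times <- read_interval_min * (seq_len(n_reads) - 1L)
    kin <- grid[rep(seq_len(nrow(grid)), each = n_reads)]
    kin$time_min <- rep(times, nrow(grid))
    slope <- kin$activity * kin$protein_mg
    kin$rfu <- 100 + slope * kin$time_min +
      stats::rnorm(nrow(kin), 0, rfu_noise_sd)

    paths <- list(
      kinetics = file.path(out_dir, "kinetics.csv"),
      protein = file.path(out_dir, "protein.csv"),
      layout = file.path(out_dir, "layout.csv"),
      manifest = file.path(out_dir, "manifest.csv"),
      gene_map = file.path(out_dir, "gene_map.csv"),
      truth = file.path(out_dir, "screen_truth.json"))
    data.table::fwrite(kin[, c("plate_id", "well", "time_min", "rfu")],
                       paths$kinetics)
    data.table::fwrite(grid[, c("plate_id", "well", "protein_mg")],
                       paths$protein)
    data.table::fwrite(grid[, c("plate_id", "well", "role", "sirna_id")],
                       paths$layout)
    data.table::fwrite(manifest, paths$manifest)
    data.table::fwrite(data.table::data.table(sirna_id = sirna_ids,
                                              gene_id = gene_ids),
                       paths$gene_map)
    truth <- list(
      effects = as.list(effects), spiked = sirna_ids[spiked],
      position_factors = as.list(pos_factor),
      plate_scales = as.list(plate_scales),
      control_effects = as.list(control_effects),
      control_positions = as.list(ctrl),
      noise_sd = noise_sd, replicates = replicates,
      n_sirna = n_sirna, seed = seed)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    list(paths = paths, truth = truth)
  })
}

#' Simulate an ontology, annotations, and a study set with planted
#' enrichment
#'
#' Builds a layered random DAG under a single root (every term at layer l
#' draws its parents from layer l-1, so a term's level equals its layer),
#' annotates genes to terms independently at per-term background rates,
#' and over-annotates `n_planted` childless terms at layer >= 3 in a
#' designated study set by factor `fold` (childless so propagation leaves
#' the planted fold exact). The library list (a superset of the study
#' genes, emulating the screened library) shares only the background
#' rates, so planted terms differ between study and library as the QC
#' filter expects.
#'
#' @param out_dir directory to write into.
#' @param n_terms,n_genes ontology and gene-universe sizes.
#' @param depth number of layers below the root (>= 3 so planted terms can
#'   sit below the level-2 exclusion zone).
#' @param n_planted number of planted enriched terms.
#' @param fold over-annotation factor (> 1) for planted terms in the study
#'   set.
#' @param study_size number of study genes.
#' @param library_fraction fraction of genes in the library list.
#' @param base_rate_range per-term background annotation probability range
#'   at the deepest layer.
#' @param rate_growth multiplicative growth of direct annotation rates per
#'   layer toward the root (rates capped at 0.3): shallow categories
#'   annotate many genes, as in real ontologies.
#' @param seed integer RNG seed.
#' @return list: `paths` (obo, gaf, study, population, library, truth) and
#'   `truth` (edges, planted terms, per-term rates, study genes).
#' @export
generate_ontology <- function(out_dir, n_terms = 150L, n_genes = 1000L,
                              depth = 5L, n_planted = 2L, fold = 10,
                              study_size = 130L, library_fraction = 0.4,
                              base_rate_range = c(0.01, 0.04),
                              rate_growth = 2.5, seed = 1L) {
  if (depth < 3L) stop("depth must be >= 3 so planted terms can sit below level 2")
  if (n_planted > 0L && fold <= 1) stop("fold must exceed 1 when planting terms")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    ids <- sprintf("GO:SYN%04d", seq_len(n_terms))
    root <- ids[1]
    # layer sizes roughly equal; layer 0 is the root alone
    layer <- c(0L, sort(rep_len(seq_len(depth), n_terms - 1L)))
    parents <- vector("list", n_terms)
    names(parents) <- ids
    parents[[root]] <- character(0)
    for (i in seq_len(n_terms)[-1]) {
      pool <- ids[layer == layer[i] - 1L]
      n_par <- min(length(pool), sample(1:2, 1))
      parents[[ids[i]]] <- sort(sample(pool, n_par))
    }
    genes <- sprintf("gene%04d", seq_len(n_genes))
    study <- sort(sample(genes, study_size))
    library_genes <- sort(unique(c(study,
      sample(genes, round(library_fraction * n_genes)))))
    # plant on childless terms at layer >= 3: propagation then adds no
    # background genes to a planted term, so its fold enrichment is exact
    is_parent <- ids %in% unlist(parents, use.names = FALSE)
    deep <- ids[layer >= 3L & !is_parent]
    if (n_planted > length(deep)) {
      stop("not enough childless terms below level 2 to plant ", n_planted)
    }
    planted <- if (n_planted > 0L) sort(sample(deep, n_planted)) else character(0)
    # direct rates grow toward the root (shallow categories annotate many
    # genes, as in real ontologies), capped at 0.3; conditioning on parent
    # unions is then informative rather than saturated
    rate <- stats::setNames(
      pmin(0.3, stats::runif(n_terms, base_rate_range[1], base_rate_range[2]) *
             rate_growth^(depth - layer)), ids)
    # direct annotations: gene x term Bernoulli(rate), boosted for planted
    # terms in study genes
    ann <- list()
    for (t in ids[-1]) {
      p <- rep(rate[[t]], n_genes)
      if (t %in% planted) {
        p[genes %in% study] <- pmin(1, fold * rate[[t]])
      }
      hit <- stats::runif(n_genes) < p
      ann[[t]] <- genes[hit]
    }
    direct_terms <- split(
      rep(names(ann), lengths(ann)),
      unlist(ann, use.names = FALSE))
    annots <- structure(list(direct = lapply(direct_terms, unique),
                             propagated = NULL),
                        class = "annotation_set")

    paths <- list(obo = file.path(out_dir, "ontology.obo"),
                  gaf = file.path(out_dir, "annotations.gaf"),
                  study = file.path(out_dir, "study_genes.txt"),
                  population = file.path(out_dir, "population_genes.txt"),
                  library = file.path(out_dir, "library_genes.txt"),
                  truth = file.path(out_dir, "ontology_truth.json"))
    obo <- c("format-version: 1.2", "")
    for (i in seq_len(n_terms)) {
      ps <- parents[[ids[i]]]
      stanza <- c("[Term]",
                  paste0("id: ", ids[i]),
                  paste0("name: synthetic term ", i),
                  "namespace: biological_process",
                  if (length(ps)) paste0("is_a: ", ps),
                  "")
      obo <- c(obo, stanza)
    }
    writeLines(obo, paths$obo)
    gaf_gene <- rep(names(annots$direct), lengths(annots$direct))
    gaf_term <- unlist(annots$direct, use.names = FALSE)
    gaf <- paste("SYNDB", gaf_gene, gaf_gene, "", gaf_term, "SYNREF:1",
                 "IEA", "", "P", "", "", "protein", "taxon:9606",
                 "20260101", "SYN", "", "", sep = "\t")
    writeLines(c("!gaf-version: 2.1", gaf), paths$gaf)
    writeLines(study, paths$study)
    writeLines(genes, paths$population)
    writeLines(library_genes, paths$library)
    truth <- list(root = root, layers = as.list(stats::setNames(layer, ids)),
                  parents = parents, planted = planted,
                  rates = as.list(rate), study = study,
                  library = library_genes, fold = fold, seed = seed)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    list(paths = paths, truth = truth, annots = annots)
  })
}

#' Simulate an interactome with planted hit structure
#'
#' Random background graph plus planted structure with exactly known
#' recovery behavior: a clique of seed genes (pairwise direct edges), seed
#' pairs bridged by a dedicated single connector node, and decoy seeds
#' attached only to background nodes. Background edges touch only
#' background nodes, so the planted clique is exactly the direct-connection
#' network and the bridge connectors are exactly the 1-intervening
#' shortest-path connectors.
#'
#' @param out_dir directory to write into.
#' @param n_nodes total nodes (background + planted).
#' @param n_edges background edges among background nodes.
#' @param n_seed_clique planted clique size.
#' @param n_bridges number of bridged seed pairs.
#' @param n_decoys seeds attached only to background nodes.
#' @param seed integer RNG seed.
#' @return list: `paths` (sif, seeds, truth) and `truth` (clique, bridges
#'   as from/connector/to triples, decoys, all seeds).
#' @export
generate_interactome <- function(out_dir, n_nodes = 200L, n_edges = 400L,
                                 n_seed_clique = 4L, n_bridges = 3L,
                                 n_decoys = 2L, seed = 1L) {
  n_special <- n_seed_clique + 3L * n_bridges + n_decoys
  if (n_special > n_nodes) stop("planted structure larger than node count")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    nodes <- sprintf("N%04d", seq_len(n_nodes))
    clique <- nodes[seq_len(n_seed_clique)]
    bridge_nodes <- nodes[n_seed_clique + seq_len(3L * n_bridges)]
    bridges <- matrix(bridge_nodes, ncol = 3L, byrow = TRUE,
                      dimnames = list(NULL, c("from", "connector", "to")))
    decoys <- nodes[n_seed_clique + 3L * n_bridges + seq_len(n_decoys)]
    background <- setdiff(nodes, c(clique, bridge_nodes, decoys))

    edges <- list()
    if (length(clique) > 1L) {
      cc <- t(utils::combn(clique, 2L))
      edges$clique <- data.table::data.table(from = cc[, 1], to = cc[, 2],
                                             relation = "direct")
    }
    for (b in seq_len(n_bridges)) {
      edges[[paste0("bridge", b)]] <- data.table::data.table(
        from = c(bridges[b, "from"], bridges[b, "connector"]),
        to = c(bridges[b, "connector"], bridges[b, "to"]),
        relation = "direct")
    }
    # decoy attachment nodes are disjoint across decoys, so no background
    # node can become an unplanned single connector between two decoys
    if (length(decoys)) {
      anchors <- matrix(sample(background, 2L * length(decoys)), ncol = 2L)
      for (d in seq_along(decoys)) {
        edges[[paste0("decoy_", decoys[d])]] <- data.table::data.table(
          from = decoys[d], to = anchors[d, ], relation = "indirect")
      }
    }
    bg_from <- sample(background, n_edges, replace = TRUE)
    bg_to <- sample(background, n_edges, replace = TRUE)
    ok <- bg_from != bg_to
    edges$background <- data.table::data.table(
      from = bg_from[ok], to = bg_to[ok],
      relation = sample(c("direct", "indirect"), sum(ok), replace = TRUE))
    all_edges <- data.table::rbindlist(edges)

    seeds <- sort(c(clique, bridges[, "from"], bridges[, "to"], decoys))
    paths <- list(sif = file.path(out_dir, "interactome.sif"),
                  seeds = file.path(out_dir, "seed_genes.txt"),
                  truth = file.path(out_dir, "interactome_truth.json"))
    writeLines(paste(all_edges$from, all_edges$relation, all_edges$to),
               paths$sif)
    writeLines(seeds, paths$seeds)
    truth <- list(clique = clique,
                  bridges = as.data.frame(bridges),
                  decoys = decoys, seeds = seeds, seed = seed)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    list(paths = paths, truth = truth)
  })
}
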