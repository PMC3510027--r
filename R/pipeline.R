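#' Packaged suppressor table (published screen hit list)
#'
#' The 130-row suppressor table shipped with the package: gene symbol,
#' Entrez id, gene name, functional class, and the normalized caspase
#' activity mean and standard error of each hit pool (fractions of
#' negative control; 1 = no change). Every row satisfies the hit rule
#' mean + SEM < 0.683 under the screen-wide SD of 0.317.
#'
#' @return data.table (gene_symbol, entrez_id, gene_name, functional_class,
#'   mean, sem) in the published rank order (ascending mean).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_suppressors.tsv",
                      package = "screensift", mustWork = TRUE)
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("gene_symbol",
                                                    "gene_name",
                                                    "functional_class")))
}

#' Read a flat key-value run configuration
#'
#' Lines are `key = value`; blank lines, `#` comments and `[section]`
#' headers (organizational only) are ignored. Known numeric parameters are
#' coerced.
#'
#' @param path config file.
#' @return named list of config values.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "[")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  config <- stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) trimws(m[2]), character(1)))
  numeric_keys <- c("alpha", "min_level", "qc_alpha", "sd_override",
                    "max_intervening", "controls_per_role", "min_replicates")
  for (key in intersect(names(config), numeric_keys)) {
    config[[key]] <- as.numeric(config[[key]])
  }
  config
}

# Runs one pipeline stage; any error is re-signalled as a classed
# condition carrying the stage name, so callers (and shells running the
# analysis scripts) can tell which stage failed.
#' @keywords internal
run_stage <- function(stage, log, expr) {
  log(paste0("stage ", stage, ": start"))
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("screensift_stage_error", "error", "condition"),
                   list(message = paste0("stage '", stage, "' failed: ",
                                         conditionMessage(e)),
                        call = NULL, stage = stage)))
  })
}

#' @keywords internal
require_files <- function(config, keys, stage) {
  for (key in keys) {
    if (is.null(config[[key]])) {
      stop("config key '", key, "' required by stage ", stage)
    }
    if (!file.exists(config[[key]])) {
      stop("input file for '", key, "' not found: ", config[[key]])
    }
  }
}

#' Run the end-to-end screen pipeline
#'
#' Orchestrates the five analysis stages — `activity` (kinetic slopes to
#' per-well activities), `normalize` (position then negative-control
#' normalization), `call_hits` (replicate aggregation and the mean + SEM
#' hit rule), `enrich` (Parent-Child-Union GO enrichment with BH, level
#' and QC filters) and `network` (hit networks over an interactome) —
#' writing stage outputs with stable names plus a machine-readable run
#' manifest (input checksums, parameters, package version, per-stage row
#' counts) into the output directory. The `enrich` and `network` stages
#' run when their input keys are configured and are recorded as skipped
#' otherwise. Any stage error aborts the run with a condition of class
#' `screensift_stage_error` naming the failing stage.
#'
#' @param config named list (or path to a file readable by
#'   [read_run_config()]) with input paths (`kinetics`, `protein`,
#'   `layout`, `manifest`, optional `gene_map`, `obo`, `gaf`,
#'   `population`, `library`, `study`, `interactome`, `seeds`, `focus`),
#'   parameters (`alpha`, `min_level`, `qc_alpha`, `sd_override`,
#'   `max_intervening`, `network_mode` = "direct" or "paths",
#'   `controls_per_role`) and `out_dir`.
#' @param quiet suppress progress messages.
#' @return the output directory path, invisibly; `manifest.json` inside it
#'   describes the run.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log <- function(msg) {
    line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", msg)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  param_or <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  stages <- list()
  outputs <- character(0)

  activities <- run_stage("activity", log, {
    require_files(config, c("kinetics", "protein", "layout"), "activity")
    act <- compute_plate_activities(
      config$kinetics, config$protein, config$layout,
      controls_per_role = as.integer(param_or("controls_per_role", 3L)))
    write_activity_tsv(act, file.path(out_dir, "activities.tsv"))
    act
  })
  outputs["activity"] <- "activities.tsv"
  stages$activity <- list(status = "ok", rows = nrow(activities))

  normalized <- run_stage("normalize", log, {
    require_files(config, "manifest", "normalize")
    manifest <- data.table::fread(config$manifest,
                                  colClasses = list(character = "plate_id"))
    norm <- normalize_screen(activities, manifest)
    data.table::fwrite(norm, file.path(out_dir, "normalized.tsv"), sep = "\t")
    norm
  })
  outputs["normalize"] <- "normalized.tsv"
  stages$normalize <- list(status = "ok", rows = nrow(normalized))

  summary <- run_stage("call_hits", log, {
    gene_map <- if (!is.null(config$gene_map)) {
      data.table::fread(config$gene_map, colClasses = "character")
    }
    records <- summarize_screen(normalized, gene_map)
    sigma <- if (!is.null(config$sd_override)) {
      as.numeric(config$sd_override)
    } else {
      screen_sd(records$mean)
    }
    s <- call_hits(records, sigma)
    tab <- s$records[, c("sirna_id", "gene_id", "n", "mean", "sem", "hit",
                         "enhancer")]
    data.table::fwrite(tab, file.path(out_dir, "screen_summary.tsv"),
                       sep = "\t")
    data.table::fwrite(
      gene_rollup(s$records)[, c("gene_id", "sirna_id", "n", "mean", "sem",
                                 "hit")],
      file.path(out_dir, "gene_rollup.tsv"), sep = "\t")
    s
  })
  outputs["call_hits"] <- "screen_summary.tsv"
  stages$call_hits <- list(status = "ok", rows = nrow(summary$records),
                           hits = nrow(summary$hits),
                           screen_sd = summary$screen_sd,
                           cutoff = summary$cutoff)

  if (!is.null(config$obo)) {
    enrichment <- run_stage("enrich", log, {
      require_files(config, c("obo", "gaf", "population"), "enrich")
      dag <- parse_obo(config$obo)
      annots <- propagate(dag, parse_gaf(config$gaf))
      population <- readLines(config$population)
      study <- if (!is.null(config$study)) {
        readLines(config$study)
      } else {
        intersect(unique(summary$hits$gene_id), population)
      }
      library_genes <- if (!is.null(config$library)) {
        readLines(config$library)
      }
      res <- enrich(dag, annots, study, population, library_genes,
                    alpha = param_or("alpha", 0.05),
                    min_level = as.integer(param_or("min_level", 2L)),
                    qc_alpha = param_or("qc_alpha", 0.05))
      data.table::fwrite(res, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t")
      export_dag_graph(res, dag, file.path(out_dir, "enriched_terms.dot"))
      res
    })
    outputs["enrich"] <- "enrichment.tsv"
    stages$enrich <- list(status = "ok", rows = nrow(enrichment),
                          kept = sum(enrichment$kept))
  } else {
    log("stage enrich: skipped (no ontology configured)")
    stages$enrich <- list(status = "skipped")
  }

  if (!is.null(config$interactome)) {
    net <- run_stage("network", log, {
      require_files(config, "interactome", "network")
      g <- read_interactome(config$interactome)
      seeds <- if (!is.null(config$seeds)) {
        readLines(config$seeds)
      } else {
        unique(summary$hits$gene_id)
      }
      mode <- param_or("network_mode", "direct")
      n <- if (identical(mode, "paths")) {
        shortest_path_network(
          g, seeds,
          max_intervening = as.integer(param_or("max_intervening", 1L)))
      } else {
        direct_subnetwork(g, seeds)
      }
      if (!is.null(config$focus)) n <- add_focus_node(n, g, config$focus)
      data.table::fwrite(degree_report(n),
                         file.path(out_dir, "network_degrees.tsv"),
                         sep = "\t")
      write_network_graphml(n, file.path(out_dir, "network.graphml"))
      write_network_dot(n, file.path(out_dir, "network.dot"))
      n
    })
    outputs["network"] <- "network_degrees.tsv"
    stages$network <- list(status = "ok", nodes = nrow(net$members),
                           edges = nrow(net$edges))
  } else {
    log("stage network: skipped (no interactome configured)")
    stages$network <- list(status = "skipped")
  }

  input_keys <- intersect(names(config),
                          c("kinetics", "protein", "layout", "manifest",
                            "gene_map", "obo", "gaf", "study", "population",
                            "library", "interactome", "seeds"))
  checksums <- lapply(input_keys, function(k) {
    unname(tools::md5sum(config[[k]]))
  })
  names(checksums) <- input_keys
  params <- config[setdiff(names(config), c(input_keys, "out_dir"))]
  manifest <- list(
    package = "screensift",
    version = as.character(utils::packageVersion("screensift")),
    inputs = checksums, parameters = params, stages = stages,
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("run complete")
  invisible(out_dir)
}
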