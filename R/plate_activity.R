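#' Read kinetic fluorescence plate data
#'
#' Parses a long-format CSV of kinetic reads (one row per plate, well and
#' time point) into one record per (plate, well) with the time series
#' sorted ascending. Row order in the file is irrelevant.
#'
#' @param path CSV with header `plate_id,well,time_min,rfu`. `time_min` is
#'   minutes since the start of the read; `rfu` relative fluorescence units.
#' @return a `data.table` keyed by (plate_id, well) with list columns
#'   `times` and `rfu`, one row per well read.
#' @export
read_kinetic_csv <- function(path) {
  dt <- read_numeric_csv(path, c("plate_id", "well", "time_min", "rfu"),
                         numeric_cols = c("time_min", "rfu"))
  dup <- dt[duplicated(dt, by = c("plate_id", "well", "time_min"))]
  if (nrow(dup)) {
    stop("duplicate kinetic read for (", dup$plate_id[1], ", ", dup$well[1],
         ", t=", dup$time_min[1], " min) in ", path)
  }
  if (any(!is.finite(dt$rfu))) stop("non-finite rfu values in ", path)
  data.table::setorder(dt, plate_id, well, time_min)
  reads <- dt[, list(times = list(time_min), rfu = list(rfu)),
              by = c("plate_id", "well")]
  n_t <- vapply(reads$times, length, integer(1))
  if (any(n_t < 2L)) {
    w <- which(n_t < 2L)[1]
    stop("well ", reads$well[w], " on plate ", reads$plate_id[w],
         " has fewer than 2 time points")
  }
  reads[]
}

# Shared CSV reader: checks the header, flags non-numeric fields with the
# offending line number (header = line 1).
#' @keywords internal
read_numeric_csv <- function(path, expected_cols, numeric_cols) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (!identical(names(dt), expected_cols)) {
    stop("expected header ", paste(expected_cols, collapse = ","),
         " in ", path, "; got ", paste(names(dt), collapse = ","))
  }
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(val) & !is.na(dt[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " ('", dt[[col]][bad[1]], "') at line ",
           bad[1] + 1L, " of ", path)
    }
    data.table::set(dt, j = col, value = val)
  }
  dt
}

#' Ordinary least-squares slope of a kinetic read
#'
#' The activity readout is the rate of fluorescence increase, so each well's
#' read series is reduced to its OLS slope in RFU per minute. The estimator
#' is the closed-form normal-equations slope (`cov(t, y) / var(t)`), exact
#' on noiseless linear input for any time spacing. Negative slopes are
#' returned unmodified; downstream normalization operates on raw values.
#'
#' @param times numeric vector of read times in minutes, at least 2 distinct.
#' @param rfu numeric vector of fluorescence values, same length.
#' @return slope in RFU per minute.
#' @examples
#' fit_kinetic_slope(c(0, 44, 88), c(0, 88, 176))  # 2
#' @export
fit_kinetic_slope <- function(times, rfu) {
  if (length(times) != length(rfu)) stop("times and rfu lengths differ")
  if (length(times) < 2L) stop("need at least 2 time points")
  if (stats::var(times) == 0) stop("degenerate time axis: all times identical")
  stats::cov(times, rfu) / stats::var(times)
}

#' Caspase 3/7 activity from slope and protein mass
#'
#' Activity is the change in RFU per minute per milligram of total protein
#' in the well: `slope / protein_mg`.
#'
#' @param slope RFU per minute.
#' @param protein_mg milligrams total protein (from a BCA assay), > 0.
#' @return activity in RFU min^-1 mg^-1 (vectorized).
#' @export
compute_activity <- function(slope, protein_mg) {
  if (any(!is.finite(protein_mg)) || any(protein_mg <= 0)) {
    stop("nonpositive protein mass")
  }
  slope / protein_mg
}

#' Read per-well protein masses
#' @param path CSV with header `plate_id,well,protein_mg`.
#' @return data.table (plate_id, well, protein_mg).
#' @export
read_protein_csv <- function(path) {
  read_numeric_csv(path, c("plate_id", "well", "protein_mg"), "protein_mg")
}

#' Read plate layout maps
#'
#' Each well has exactly one role: `test` (carries an siRNA pool) or one of
#' the four control roles (`neg_control`, `pos_control`, `tox_control_nt`,
#' `tox_control_casp3`). Test wells carry an `sirna_id`; control wells an
#' empty one.
#'
#' @param path CSV with header `plate_id,well,role,sirna_id`.
#' @param controls_per_role expected number of wells per control role on
#'   every plate (default 3).
#' @return data.table (plate_id, well, role, sirna_id).
#' @export
read_layout_csv <- function(path, controls_per_role = 3L) {
  dt <- read_numeric_csv(path, c("plate_id", "well", "role", "sirna_id"),
                         character(0))
  assert_roles(dt$role)
  dup <- dt[duplicated(dt, by = c("plate_id", "well"))]
  if (nrow(dup)) {
    stop("well ", dup$well[1], " on plate ", dup$plate_id[1],
         " has more than one role")
  }
  role <- NULL # data.table NSE
  counts <- dt[role != "test", .N, by = c("plate_id", "role")]
  off <- counts[counts$N != controls_per_role]
  if (nrow(off)) {
    stop("plate ", off$plate_id[1], " has ", off$N[1], " ", off$role[1],
         " wells; expected ", controls_per_role)
  }
  dt
}

#' Compute per-well activities for a screen
#'
#' Joins kinetic reads, protein masses and layouts, fits each well's OLS
#' slope and divides by the well's protein mass.
#'
#' @param kinetics path to the kinetic CSV (see [read_kinetic_csv()]).
#' @param protein path to the protein CSV (see [read_protein_csv()]).
#' @param layout path to the layout CSV (see [read_layout_csv()]).
#' @param controls_per_role passed to [read_layout_csv()].
#' @return data.table (plate_id, well, role, sirna_id, slope, protein_mg,
#'   activity), one row per laid-out well.
#' @export
compute_plate_activities <- function(kinetics, protein, layout,
                                     controls_per_role = 3L) {
  reads <- read_kinetic_csv(kinetics)
  prot <- read_protein_csv(protein)
  lay <- read_layout_csv(layout, controls_per_role)
  reads$slope <- vapply(seq_len(nrow(reads)), function(i) {
    fit_kinetic_slope(reads$times[[i]], reads$rfu[[i]])
  }, numeric(1))
  out <- merge(lay, reads[, c("plate_id", "well", "slope")],
               by = c("plate_id", "well"))
  if (nrow(out) < nrow(lay)) {
    miss <- lay[!reads, on = c("plate_id", "well")]
    stop("no kinetic reads for well ", miss$well[1], " on plate ",
         miss$plate_id[1])
  }
  out <- merge(out, prot, by = c("plate_id", "well"))
  out$activity <- compute_activity(out$slope, out$protein_mg)
  data.table::setcolorder(out, c("plate_id", "well", "role", "sirna_id",
                                 "slope", "protein_mg", "activity"))
  data.table::setorder(out, plate_id, well)
  out[]
}

#' Write an activity table as TSV
#' @param activities output of [compute_plate_activities()].
#' @param path destination file.
#' @export
write_activity_tsv <- function(activities, path) {
  data.table::fwrite(activities, path, sep = "\t")
  invisible(path)
}

#' Read an activity TSV written by [write_activity_tsv()]
#' @param path TSV path.
#' @return data.table with the activity-table columns.
#' @export
read_activity_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("plate_id", "well", "role", "sirna_id")))
  need <- c("plate_id", "well", "role", "sirna_id", "slope", "protein_mg",
            "activity")
  if (!all(need %in% names(dt))) {
    stop("activity TSV ", path, " missing column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  dt
}
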