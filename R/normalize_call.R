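#' Position-effect normalization across a day's plates
#'
#' Plates screened on one day share systematic well-position biases (edge
#' evaporation, dispensing gradients). Each well's value is divided by the
#' mean of that grid position across all plates in the batch; the siRNA
#' library is arranged by gene family, so per-position averaging is used
#' instead of plate-mean scaling. Control wells sit at fixed positions and
#' are included in the per-position averages (their position average is
#' over like wells).
#'
#' @param batch data.table with columns `plate_id`, `well`, `value` (one row
#'   per well) covering the plates of one screening-day batch.
#' @param value_col name of the value column (default `"activity"`).
#' @return the same table with `value_col` replaced by the
#'   position-normalized value; the per-position mean of the output is 1.
#' @export
position_normalize <- function(batch, value_col = "activity") {
  batch <- data.table::as.data.table(batch)
  if (!nrow(batch)) stop("empty batch")
  geoms <- batch[, list(wells = list(sort(unique(well)))), by = "plate_id"]
  ref <- geoms$wells[[1]]
  same <- vapply(geoms$wells, identical, logical(1), y = ref)
  if (!all(same)) {
    stop("mixed plate geometries in batch: plate ",
         geoms$plate_id[!same][1], " differs from plate ", geoms$plate_id[1])
  }
  v <- batch[[value_col]]
  pos_mean <- stats::ave(v, batch$well, FUN = mean)
  zero <- pos_mean == 0
  if (any(zero)) {
    stop("per-position mean is 0 at well ", batch$well[zero][1])
  }
  data.table::set(batch, j = value_col, value = v / pos_mean)
  batch[]
}

#' Negative-control normalization within a plate
#'
#' Expresses every well as a fraction of the plate's negative-control
#' activity (mutant construct + non-targeting siRNA): each value is divided
#' by the arithmetic mean of the plate's `neg_control` wells, so the
#' negative-control mean maps to 1. Applied after position normalization.
#'
#' @param plate data.table with columns `well`, `role`, and the value column
#'   for one plate.
#' @inheritParams position_normalize
#' @return the table with values as fractions of negative control.
#' @export
control_normalize <- function(plate, value_col = "activity") {
  plate <- data.table::as.data.table(plate)
  neg <- plate[[value_col]][plate$role == "neg_control"]
  if (!length(neg)) stop("plate has no neg_control wells")
  ref <- mean(neg)
  if (!is.finite(ref) || ref <= 0) {
    stop("neg_control mean is ", ref, "; must be positive")
  }
  data.table::set(plate, j = value_col, value = plate[[value_col]] / ref)
  plate[]
}

#' Normalize a whole screen
#'
#' Applies the two normalization stages to every batch: position
#' normalization across the plates of each screening day, then per-plate
#' scaling to the negative-control mean.
#'
#' @param activities activity table from [compute_plate_activities()] (or
#'   [read_activity_tsv()]).
#' @param manifest data.table mapping `plate_id` to `batch_id` (screening
#'   day) and `replicate_index`.
#' @return the activity table with an added `normalized` column (unitless,
#'   1 = negative control) and the manifest columns joined on.
#' @export
normalize_screen <- function(activities, manifest) {
  manifest <- data.table::as.data.table(manifest)
  need <- c("plate_id", "batch_id", "replicate_index")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  act <- merge(data.table::as.data.table(activities), manifest,
               by = "plate_id")
  if (!nrow(act)) stop("no plates in common between activities and manifest")
  act$normalized <- act$activity
  parts <- split(act, by = "batch_id")
  parts <- lapply(parts, function(b) {
    b <- position_normalize(b, "normalized")
    plates <- split(b, by = "plate_id")
    data.table::rbindlist(lapply(plates, control_normalize, "normalized"))
  })
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, plate_id, well)
  out[]
}

#' Aggregate normalized replicate values for one siRNA pool
#'
#' @param values numeric vector of normalized replicate values (fractions of
#'   negative control), length >= 2.
#' @return list with `values`, `n`, `mean` (arithmetic) and `sem` (sample
#'   SD with the n-1 denominator, divided by sqrt(n)).
#' @export
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 replicates")
  list(values = values, n = length(values), mean = mean(values),
       sem = stats::sd(values) / sqrt(length(values)))
}

#' Screen-wide standard deviation of per-siRNA means
#'
#' The hit cutoff is one screen-wide SD below the normalized mean of 1; this
#' computes that SD over all per-siRNA means. The sample (n-1) denominator
#' is the default; at thousands of siRNAs the choice is negligible.
#'
#' @param means numeric vector of per-siRNA normalized means, length >= 2.
#' @param denominator `"sample"` (n-1) or `"population"` (n).
#' @return the screen SD (unitless).
#' @export
screen_sd <- function(means, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  means <- means[!is.na(means)]
  if (length(means) < 2L) stop("need at least 2 per-siRNA means")
  s <- stats::sd(means)
  if (denominator == "population") {
    s <- s * sqrt((length(means) - 1) / length(means))
  }
  s
}

#' Call suppressor hits by the mean + SEM criterion
#'
#' An siRNA pool is a suppressor hit if the upper end of its confidence
#' interval (mean + SEM) lies strictly below the cutoff `1 - sigma`, i.e.
#' more than one screen-wide SD below the screen mean of 1. Hits are ranked
#' ascending by mean (strongest suppression first). The symmetric enhancer
#' flag (`mean - sem > 1 + sigma`) is provided as a convenience only.
#'
#' @param records data.table with columns `sirna_id`, `mean`, `sem` (and
#'   optionally `gene_id`, `n`), one row per siRNA pool.
#' @param sigma screen-wide SD; must lie in (0, 1). Defaults to
#'   `screen_sd(records$mean)`.
#' @return list of class `screen_summary`: `records` (all rows, ranked by
#'   mean, with `hit` and `enhancer` flags), `screen_sd`, `cutoff`
#'   (`1 - sigma`), and `hits` (the flagged subset).
#' @export
call_hits <- function(records, sigma = screen_sd(records$mean)) {
  records <- data.table::as.data.table(records)
  if (!all(c("sirna_id", "mean", "sem") %in% names(records))) {
    stop("records must have columns sirna_id, mean, sem")
  }
  if (!is.finite(sigma) || sigma <= 0 || sigma >= 1) {
    stop("screen SD must lie in (0, 1); got ", sigma)
  }
  cutoff <- 1 - sigma
  records$hit <- records$mean + records$sem < cutoff
  records$enhancer <- records$mean - records$sem > 1 + sigma
  data.table::setorder(records, mean, sirna_id)
  structure(list(records = records[], screen_sd = sigma, cutoff = cutoff,
                 hits = records[records$hit]),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary: ", nrow(x$records), " siRNA pools\n",
      "  screen SD ", format(x$screen_sd, digits = 4),
      ", hit cutoff mean + SEM < ", format(x$cutoff, digits = 4), "\n",
      "  ", nrow(x$hits), " suppressor hits, ",
      sum(x$records$enhancer), " enhancer-flagged\n", sep = "")
  invisible(x)
}

#' Summarize a normalized screen into per-siRNA records
#'
#' Groups the normalized test-well values by siRNA pool, drops missing
#' replicates pairwise, and aggregates mean and SEM per pool. Pools with
#' fewer than 2 surviving replicates are dropped (reported via attribute
#' `dropped`). Duplicate pools targeting the same gene stay distinct
#' records; see [gene_rollup()] for the gene-level view.
#'
#' @param normalized output of [normalize_screen()].
#' @param gene_map optional data.table (sirna_id, gene_id); when absent the
#'   gene id defaults to the siRNA id.
#' @return data.table (sirna_id, gene_id, n, mean, sem) with a list column
#'   `values` of the normalized replicates.
#' @export
summarize_screen <- function(normalized, gene_map = NULL) {
  norm <- data.table::as.data.table(normalized)
  tests <- norm[norm$role == "test" & !is.na(norm$normalized) &
                  !is.na(norm$sirna_id) & nzchar(norm$sirna_id)]
  if (!nrow(tests)) stop("no test wells with normalized values")
  recs <- tests[, {
    agg <- if (.N >= 2L) aggregate_replicates(normalized) else NULL
    if (is.null(agg)) {
      list(values = list(normalized), n = .N,
           mean = NA_real_, sem = NA_real_)
    } else {
      list(values = list(agg$values), n = agg$n, mean = agg$mean,
           sem = agg$sem)
    }
  }, by = "sirna_id"]
  dropped <- recs$sirna_id[is.na(recs$mean)]
  recs <- recs[!is.na(recs$mean)]
  if (!is.null(gene_map)) {
    gene_map <- data.table::as.data.table(gene_map)
    recs <- merge(recs, gene_map[, c("sirna_id", "gene_id")],
                  by = "sirna_id", all.x = TRUE)
    recs$gene_id[is.na(recs$gene_id)] <- recs$sirna_id[is.na(recs$gene_id)]
  } else {
    recs$gene_id <- recs$sirna_id
  }
  data.table::setcolorder(recs, c("sirna_id", "gene_id", "n", "mean", "sem"))
  data.table::setattr(recs, "dropped", dropped)
  recs[]
}

#' Gene-level roll-up of duplicate siRNA pools
#'
#' Screening libraries carry duplicate pools for some genes. The roll-up
#' keeps, per gene, the pool with the smallest mean + SEM (the pool that
#' would be called first), reported separately from the per-pool records.
#'
#' @param records per-pool records (from [summarize_screen()] or
#'   [call_hits()]`$records`).
#' @return data.table with one row per gene_id.
#' @export
gene_rollup <- function(records) {
  records <- data.table::as.data.table(records)
  score <- records$mean + records$sem
  ord <- order(records$gene_id, score, records$sirna_id)
  best <- records[ord][!duplicated(gene_id)]
  data.table::setorder(best, mean, gene_id)
  best[]
}
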