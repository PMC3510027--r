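#' Predict the screen's operating point by direct Monte-Carlo simulation
#'
#' Simulates the hit-calling operating point (null hit rate, spike-in
#' recall, screen SD and cutoff) directly on the screen's noise model,
#' without generating plate files or fitting kinetic slopes: per-well
#' values `effect + N(0, noise_sd)` times log-normal position and plate
#' factors are laid out on batches of plates exactly as the screen design
#' prescribes, position- and control-normalized with plain array
#' arithmetic, aggregated over replicates, and passed through the
#' mean + SEM hit rule. Because every systematic factor and every
#' normalization denominator (shared per-position batch means, per-plate
#' negative-control means) is simulated, the prediction accounts for the
#' noise those denominators re-inject. Used as the reference against which
#' the full file-level pipeline is calibrated; useful on its own for
#' screen design (expected false-call rate, recall at a given effect
#' size).
#'
#' @param n_sirna siRNA pools to simulate (larger than the real screen for
#'   a smoother estimate, if desired).
#' @param n_spiked number of spiked suppressors among them.
#' @param effect_range suppressor effect bounds (point mass when equal).
#' @param replicates replicate plates per source plate.
#' @param plates_per_batch maximum plates per screening-day batch.
#' @param noise_sd replicate noise SD on the normalized effect scale.
#' @param position_sdlog,plate_sdlog log-normal SDs of position and plate
#'   factors.
#' @param control_effects named control-role effects (only `neg_control`
#'   enters normalization).
#' @param controls_per_role control wells per role.
#' @param seed RNG seed.
#' @return list: `null_hit_rate`, `spike_recall` (NA when `n_spiked` is
#'   0), `screen_sd`, `cutoff`, `n_null`, `n_spiked`.
#' @export
predict_operating_point <- function(n_sirna = 20000L, n_spiked = 0L,
                                    effect_range = c(0.4, 0.4),
                                    replicates = 3L, plates_per_batch = 30L,
                                    noise_sd = 0.05, position_sdlog = 0.10,
                                    plate_sdlog = 0.15,
                                    control_effects = c(neg_control = 1,
                                                        pos_control = 0.3,
                                                        tox_control_nt = 0.15,
                                                        tox_control_casp3 = 0.10),
                                    controls_per_role = 3L, seed = 1L) {
  ctrl <- default_control_layout(controls_per_role)
  wells <- plate_wells()
  test_wells <- setdiff(wells, names(ctrl))
  n_test <- length(test_wells)
  n_source <- ceiling(n_sirna / n_test)
  src_per_day <- max(1L, plates_per_batch %/% replicates)

  with_seed(seed, {
    spiked_idx <- sort(sample.int(n_sirna, n_spiked))
    effects <- rep(1, n_sirna)
    effects[spiked_idx] <- stats::runif(n_spiked, effect_range[1],
                                        effect_range[2])
    pos_factor <- stats::rlnorm(length(wells), 0, position_sdlog)
    names(pos_factor) <- wells

    rep_values <- matrix(NA_real_, n_sirna, replicates)
    neg_wells <- names(ctrl)[ctrl == "neg_control"]
    for (day_start in seq(1L, n_source, by = src_per_day)) {
      sources <- day_start:min(day_start + src_per_day - 1L, n_source)
      n_plates <- length(sources) * replicates
      # value[plate, well]: plate index runs over (source x replicate)
      eff <- matrix(1, n_plates, length(wells),
                    dimnames = list(NULL, wells))
      sirna_of <- matrix(NA_integer_, n_plates, length(wells))
      p <- 0L
      for (s in sources) {
        idx <- ((s - 1L) * n_test + 1L):min(s * n_test, n_sirna)
        for (r in seq_len(replicates)) {
          p <- p + 1L
          eff[p, names(ctrl)] <- control_effects[ctrl]
          eff[p, test_wells[seq_along(idx)]] <- effects[idx]
          sirna_of[p, match(test_wells[seq_along(idx)], wells)] <- idx
        }
      }
      raw <- (eff + stats::rnorm(length(eff), 0, noise_sd)) *
        rep(pos_factor[wells], each = n_plates) *
        stats::rlnorm(n_plates, 0, plate_sdlog)
      # position normalization: shared per-position batch means
      v1 <- sweep(raw, 2L, colMeans(raw), "/")
      # control normalization: per-plate negative-control means
      v2 <- sweep(v1, 1L, rowMeans(v1[, neg_wells, drop = FALSE]), "/")
      rep_of <- rep(rep(seq_len(replicates), length(sources)),
                    times = length(wells))
      keep <- !is.na(sirna_of)
      rep_values[cbind(sirna_of[keep], rep_of[keep])] <- v2[keep]
    }

    means <- rowMeans(rep_values)
    sems <- apply(rep_values, 1L, stats::sd) / sqrt(replicates)
    sigma <- stats::sd(means)
    cutoff <- 1 - sigma
    hit <- means + sems < cutoff
    is_spiked <- seq_len(n_sirna) %in% spiked_idx
    list(null_hit_rate = mean(hit[!is_spiked]),
         spike_recall = if (n_spiked > 0L) mean(hit[is_spiked]) else NA_real_,
         screen_sd = sigma, cutoff = cutoff,
         n_null = sum(!is_spiked), n_spiked = n_spiked)
  })
}
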