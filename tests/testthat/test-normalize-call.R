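wells96 <- plate_wells()

test_that("position normalization divides by per-position batch means", {
  vals <- matrix(5, nrow = 4, ncol = 6,
                 dimnames = list(NULL, wells96[1:6]))
  out <- position_normalize(make_batch(vals))
  expect_true(all(out$activity == 1))

  single <- position_normalize(make_batch(vals[1, , drop = FALSE]))
  expect_true(all(single$activity == 1))

  set.seed(21)
  raw <- matrix(rlnorm(30 * 96, 5, 0.4), nrow = 30,
                dimnames = list(NULL, wells96))
  pos <- rlnorm(96, 0, 0.2)
  batch <- make_batch(sweep(raw, 2, pos, "*"))
  out <- position_normalize(batch)
  ref <- oracle_position_normalize(
    data.frame(well = batch$well, value = batch$activity))
  expect_equal(out$activity, ref, tolerance = 1e-12)
  # per-position means of the output are 1
  m <- tapply(out$activity, out$well, mean)
  expect_equal(as.vector(m), rep(1, 96), tolerance = 1e-12)
})

test_that("position normalization rejects degenerate input", {
  vals <- matrix(c(1, -1), nrow = 2, ncol = 1,
                 dimnames = list(NULL, "A1"))
  expect_error(position_normalize(make_batch(vals)), "mean is 0 at well A1")

  mixed <- rbind(
    data.table::data.table(plate_id = "P1", well = c("A1", "A2"),
                           activity = 1),
    data.table::data.table(plate_id = "P2", well = c("A1", "A3"),
                           activity = 1))
  expect_error(position_normalize(mixed), "mixed plate geometries")
})

test_that("control normalization maps the negative-control mean to 1", {
  plate <- data.table::data.table(
    well = c("A1", "B1", "C1", "D1"),
    role = c("neg_control", "neg_control", "neg_control", "test"),
    activity = c(2, 2, 2, 1))
  out <- control_normalize(plate)
  expect_equal(out$activity, c(1, 1, 1, 0.5))

  set.seed(4)
  plate2 <- data.table::data.table(
    well = wells96[1:20],
    role = c(rep("neg_control", 3), rep("test", 17)),
    activity = rlnorm(20, 0, 0.3))
  out2 <- control_normalize(plate2)
  expect_equal(out2$activity, plate2$activity / mean(plate2$activity[1:3]),
               tolerance = 1e-12)
  expect_equal(mean(out2$activity[1:3]), 1)

  bad <- data.table::data.table(well = "A1", role = "neg_control",
                                activity = 0)
  expect_error(control_normalize(bad), "must be positive")
})

test_that("two-stage normalization gives all 1 on control-pattern batches", {
  # every plate equals the same pattern: position effects and the control
  # reference absorb everything
  pattern <- rlnorm(96, 3, 0.5)
  batch <- make_batch(matrix(rep(pattern, 5), nrow = 5, byrow = TRUE,
                             dimnames = list(NULL, wells96)))
  batch$role <- rep(ifelse(wells96 %in% c("A1", "B1", "C1"),
                           "neg_control", "test"), 5)
  out <- position_normalize(batch)
  out <- data.table::rbindlist(lapply(split(out, by = "plate_id"),
                                      control_normalize))
  expect_equal(out$activity, rep(1, 5 * 96), tolerance = 1e-12)
})

test_that("normalized values and hit calls are scale-invariant", {
  scr <- generate_screen(tempfile("scale"), n_sirna = 168L, seed = 13L)
  act <- compute_plate_activities(scr$paths$kinetics, scr$paths$protein,
                                  scr$paths$layout)
  man <- data.table::fread(scr$paths$manifest,
                           colClasses = list(character = "plate_id"))
  norm1 <- normalize_screen(act, man)
  act2 <- data.table::copy(act)
  act2$activity <- act2$activity * 1700
  norm2 <- normalize_screen(act2, man)
  expect_equal(norm1$normalized, norm2$normalized, tolerance = 1e-12)

  s1 <- call_hits(summarize_screen(norm1), sigma = 0.317)
  s2 <- call_hits(summarize_screen(norm2), sigma = 0.317)
  expect_equal(s1$records$hit, s2$records$hit)
})

test_that("replicate aggregation computes mean and SEM", {
  agg <- aggregate_replicates(c(0.9, 1.0, 1.1))
  expect_equal(agg$mean, 1.0)
  expect_equal(agg$sem, 0.1 / sqrt(3), tolerance = 1e-12)

  agg4 <- aggregate_replicates(rep(0.5, 4))
  expect_equal(agg4$mean, 0.5)
  expect_equal(agg4$sem, 0)

  set.seed(31)
  v <- rnorm(4, 0.7, 0.05)
  agg <- aggregate_replicates(v)
  expect_equal(agg$mean, sum(v) / 4, tolerance = 1e-12)
  expect_equal(agg$sem, sqrt(sum((v - mean(v))^2) / 3) / 2,
               tolerance = 1e-12)

  expect_error(aggregate_replicates(c(1)), "at least 2 replicates")
})

test_that("screen SD matches closed forms and recovers planted spread", {
  expect_equal(screen_sd(rep(0.8, 10)), 0)
  expect_equal(screen_sd(c(0.9, 1.1)), sqrt(0.02), tolerance = 1e-12)
  expect_equal(screen_sd(c(0.9, 1.1), denominator = "population"), 0.1)

  set.seed(99)
  means <- rnorm(7494, 1, 0.317)
  expect_equal(screen_sd(means), 0.317, tolerance = 0.01 / 0.317)
})

test_that("hit calling applies the strict mean + SEM rule and ranks hits", {
  tab <- table1_fixture()
  recs <- data.table::data.table(sirna_id = tab$gene_symbol,
                                 mean = tab$mean, sem = tab$sem)
  s <- call_hits(recs, sigma = 0.317)
  expect_equal(s$cutoff, 0.683)
  expect_true(s$records$hit[s$records$sirna_id == "IL18BP"])
  expect_true(s$records$hit[s$records$sirna_id == "TPSD1"])

  boundary <- call_hits(
    data.table::data.table(sirna_id = c("in", "out"),
                           mean = c(0.670, 0.680), sem = c(0.012, 0.010)),
    sigma = 0.317)
  expect_equal(boundary$records$hit[boundary$records$sirna_id == "in"], TRUE)
  expect_equal(boundary$records$hit[boundary$records$sirna_id == "out"],
               FALSE)

  expect_error(call_hits(recs, sigma = 0), "must lie in \\(0, 1\\)")
  expect_error(call_hits(recs, sigma = 1), "must lie in \\(0, 1\\)")
})

test_that("pools with fewer than 2 surviving replicates are dropped", {
  norm <- data.table::data.table(
    plate_id = c("P1", "P2", "P3", "P1"),
    well = "B2", role = "test",
    sirna_id = c("s1", "s1", "s1", "s2"),
    normalized = c(0.5, 0.6, NA, 0.9))
  recs <- summarize_screen(norm)
  expect_equal(recs$sirna_id, "s1")
  expect_equal(recs$n, 2L)
  expect_equal(attr(recs, "dropped"), "s2")
})

test_that("gene roll-up keeps the strongest pool per gene", {
  recs <- data.table::data.table(
    sirna_id = c("a1", "a2", "b1"),
    gene_id = c("GA", "GA", "GB"),
    n = 3L, mean = c(0.5, 0.45, 0.9), sem = c(0.01, 0.10, 0.02))
  roll <- gene_rollup(recs)
  expect_equal(nrow(roll), 2L)
  # GA: a1 has mean+sem 0.51 < a2's 0.55
  expect_equal(roll$sirna_id[roll$gene_id == "GA"], "a1")
})

test_that("enhancer convenience flag is symmetric to the hit rule", {
  recs <- data.table::data.table(
    sirna_id = c("sup", "null", "enh"),
    mean = c(0.5, 1.0, 1.5), sem = c(0.01, 0.01, 0.01))
  s <- call_hits(recs, sigma = 0.317)
  expect_equal(s$records$enhancer[match(c("sup", "null", "enh"),
                                        s$records$sirna_id)],
               c(FALSE, FALSE, TRUE))
})
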