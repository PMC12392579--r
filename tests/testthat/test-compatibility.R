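test_that("end distances measure alignment offsets from transcript ends", {
  d <- end_distances(10, 990, 1000)
  expect_equal(d, list(delta_s = 10, delta_e = 10))
  expect_equal(end_distances(0, 500, 500), list(delta_s = 0, delta_e = 0))
  expect_equal(end_distances(0, 1, 500), list(delta_s = 0, delta_e = 499))
})

test_that("end filters pass relative to the primary, -Inf disables", {
  expect_equal(end_filter_indicator(c(0, 5000, 1e9), 20, -Inf), c(1, 1, 1))
  expect_equal(end_filter_indicator(820, 20, -800), 1)  # boundary
  expect_equal(end_filter_indicator(821, 20, -800), 0)
  expect_equal(end_filter_indicator(20, 20, -800), 1)   # primary vs itself
})

test_that("score decay follows exp(-(gap)/lambda)", {
  expect_equal(score_decay(c(t1 = 900, t2 = 900)), c(t1 = 1, t2 = 1))
  sd5 <- score_decay(c(t1 = 900, t2 = 895), lambda_decay = 5)
  expect_equal(unname(sd5), c(1, exp(-1)))
  expect_equal(unname(score_decay(c(t1 = 900, t2 = 850), 5)[["t2"]]),
               exp(-10))
})

test_that("coverage profiles tally per-base reads and normalized totals", {
  idx <- make_index(c(t1 = 200L, t2 = 300L))
  rec <- make_records("r1", "t1", 100, 0, 100, TRUE, 100)
  prof <- coverage_profile(rec, idx)
  expect_equal(prof$per_base$t1, c(rep(1L, 100), rep(0L, 100)))
  expect_equal(prof$per_transcript[["t1"]], 0.5)
  expect_equal(prof$per_base$t2, rep(0L, 300))
  rec2 <- make_records(c("r1", "r2"), "t1", 100, 0, 200,
                       c(TRUE, TRUE), 200)
  prof2 <- coverage_profile(rec2, idx)
  expect_equal(prof2$per_base$t1, rep(2L, 200))
  expect_equal(prof2$per_transcript[["t1"]], 2)
})

test_that("coverage conserves total aligned bases", {
  ds <- simulate_dataset(sim_config(n_loci = 3, isoforms_per_locus = 3,
                                    n_reads = 200, seed = 5))
  rec <- dedupe_best_per_pair(ds$records)
  prof <- coverage_profile(rec, ds$index)
  expect_equal(sum(ds$index$lengths * prof$per_transcript),
               sum(rec$end - rec$start))
})

test_that("position weights are zero-shifted normalized differences", {
  prof <- structure(list(per_base = list(t = c(1L, 0L)),
                         per_transcript = c(t = 0.5)),
                    class = "coverage_profile")
  pw <- position_weights(prof, "t")
  expect_false(pw$degenerate)
  expect_equal(pw$weights, c(0, 1))

  prof3 <- structure(list(per_base = list(t = c(2L, 1L, 0L)),
                          per_transcript = c(t = 1)),
                     class = "coverage_profile")
  pw3 <- position_weights(prof3, "t")
  expect_equal(pw3$weights, c(0, 1 / 3, 2 / 3))

  # uniform coverage: all differences equal -> degenerate
  profu <- structure(list(per_base = list(t = rep(3L, 4)),
                          per_transcript = c(t = 3)),
                     class = "coverage_profile")
  expect_true(position_weights(profu, "t")$degenerate)
})

test_that("psw factors sum weights over the aligned interval", {
  expect_equal(psw_factor(0, 2, c(0, 1)), 1)     # full span
  expect_equal(psw_factor(0, 1, c(0, 1)), 0)     # only base 0
  expect_equal(psw_factor(1, 3, c(0, 1 / 3, 2 / 3)), 1)
})

test_that("non-degenerate weight vectors sum to 1 per transcript", {
  ds <- simulate_dataset(sim_config(n_loci = 3, isoforms_per_locus = 3,
                                    n_reads = 300, seed = 9))
  rec <- dedupe_best_per_pair(ds$records)
  prof <- coverage_profile(rec, ds$index)
  for (tx in ds$index$ids) {
    pw <- position_weights(prof, tx)
    if (!pw$degenerate)
      expect_equal(sum(pw$weights), 1, tolerance = 1e-12)
  }
})

test_that("compatibility rows compose decay and filters as specified", {
  idx <- make_index(c(t1 = 1000L, t2 = 1000L))
  # single alignment: sigma of the only score is 1
  rec1 <- make_records("r1", "t1", 500, 0, 900, TRUE, 900)
  cm1 <- build_compatibility(rec1, idx)
  expect_equal(as.numeric(cm1$X["r1", "t1"]), 1)
  # two transcripts, 5-point gap at lambda = 5
  rec2 <- make_records(c("r1", "r1"), c("t1", "t2"), c(900, 895),
                       c(0, 0), c(900, 900), c(TRUE, FALSE), 900)
  cm2 <- build_compatibility(rec2, idx)
  expect_equal(as.numeric(cm2$X["r1", ]), c(1, exp(-1)))
})

test_that("rows are invariant to uniform score shifts (filters off)", {
  idx <- make_index(c(t1 = 1000L, t2 = 1000L, t3 = 1000L))
  base <- make_records(rep("r1", 3), c("t1", "t2", "t3"),
                       c(900, 880, 870), 0, 800, c(TRUE, FALSE, FALSE), 800)
  shifted <- base
  shifted$score <- base$score + 123.5
  X1 <- build_compatibility(base, idx)$X
  X2 <- build_compatibility(shifted, idx)$X
  expect_equal(as.numeric(X1), as.numeric(X2), tolerance = 1e-12)
})

test_that("the primary entry is the row maximum when psw is off", {
  ds <- simulate_dataset(sim_config(n_loci = 2, isoforms_per_locus = 4,
                                    n_reads = 150, seed = 21))
  rec <- dedupe_best_per_pair(ds$records)
  cm <- build_compatibility(rec, ds$index)
  prim <- rec[rec$is_primary, ]
  for (k in sample(nrow(prim), 25)) {
    row <- cm$X[prim$read_id[k], ]
    expect_equal(as.numeric(row[prim$transcript_id[k]]), max(row))
  }
})

test_that("end filters zero non-primary entries beyond tolerance", {
  idx <- make_index(c(t1 = 1000L, t2 = 2000L))
  # candidate on t2 starts 900 into the transcript; primary starts at 10
  rec <- make_records(c("r1", "r1"), c("t1", "t2"), c(900, 899),
                      c(10, 910), c(1000, 2000), c(TRUE, FALSE), 990)
  cfg <- compat_config(beta_s = -800)
  cm <- build_compatibility(rec, idx, cfg)
  expect_equal(as.numeric(cm$X["r1", "t2"]), 0)
  expect_gt(as.numeric(cm$X["r1", "t1"]), 0)
  # filter off keeps both
  cm2 <- build_compatibility(rec, idx, compat_config())
  expect_gt(as.numeric(cm2$X["r1", "t2"]), 0)
})

test_that("psw rows with zero mass fall back to the flat factor", {
  idx <- make_index(c(t1 = 4L, t2 = 100L))
  # r1 covers only base 0 of t1 where the weight is 0 (all other reads
  # pile on the remaining bases), so its psw mass vanishes
  rec <- rbind(
    make_records("r1", "t1", 50, 0, 1, TRUE, 1),
    make_records(c("r2", "r3", "r4"), "t1", 50, 0, 4,
                 c(TRUE, TRUE, TRUE), 4))
  cm <- build_compatibility(rec, idx, compat_config(psw = TRUE))
  expect_equal(cm$n_psw_fallback, 1L)
  # the fallback row reverts to pure score decay (sigma = 1)
  expect_equal(as.numeric(cm$X["r1", "t1"]), 1)
  expect_true(all(Matrix::rowSums(cm$X) > 0))
})

test_that("compatibility TSV dump lists one row per positive entry", {
  idx <- make_index(c(t1 = 1000L, t2 = 1000L))
  rec <- make_records(c("r1", "r1"), c("t1", "t2"), c(900, 895),
                      0, 900, c(TRUE, FALSE), 900)
  cm <- build_compatibility(rec, idx)
  p <- tempfile(fileext = ".tsv")
  write_compatibility_tsv(cm, p)
  df <- read.delim(p)
  expect_equal(nrow(df), 2L)
  expect_equal(df$score, c(1, exp(-1)), tolerance = 1e-12)
})
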