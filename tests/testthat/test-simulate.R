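sheet <- littorina_sample_sheet()

test_that("null scenario gives single-copy, mismatch-free, exon-free truth", {
  d <- make_test_design(n_tx = 20, bac_len = 3000, mt_len = 1500)
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 1)
  expect_true(all(tr$copy_number == 1L))
  expect_true(all(tr$mismatch == 0L))
  expect_false(any(tr$exon_boundary))
})

test_that("truth generation is byte-identical under the same seed", {
  d <- make_test_design(n_tx = 25, bac_len = 4000, mt_len = 1500)
  t1 <- simulate_truth(d, sheet, default_scenario(), seed = 11)
  t2 <- simulate_truth(d, sheet, default_scenario(), seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_truth(d, sheet, default_scenario(), seed = 12)
  expect_false(identical(t1$copy_number, t3$copy_number))
})

test_that("duplicated fraction matches the scenario within binomial error", {
  set.seed(8)
  tx <- stats::setNames(vapply(rep(400, 2500), random_dna, character(1)),
                        sprintf("t%04d", 1:2500))
  d <- build_array_design(transcripts = tx)
  sc <- default_scenario(frac_deleted_genomic = 0)
  tr <- simulate_truth(d, sheet, sc, seed = 3)
  for (g in tr$geo_groups) {
    frac <- mean(tr$copy_number[, g] >= 2L)
    expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 2500) + 0.005)
  }
  # reference group carries no mismatches
  expect_true(all(tr$mismatch[, "saxatilis_Britain"] == 0L))
  # duplicated sets shared at roughly the configured level
  ref_set <- rownames(tr$copy_number)[tr$copy_number[, "saxatilis_Britain"] >= 2]
  other <- rownames(tr$copy_number)[tr$copy_number[, "fabalis_Sweden"] >= 2]
  expect_gt(length(intersect(ref_set, other)) / length(ref_set), 0.85)
})

test_that("scenario validation rejects impossible fractions", {
  expect_error(default_scenario(frac_duplicated = 1.2), "\\[0, 1\\]")
  div <- data.frame(geo_group = "fabalis_Sweden", frac_divergent = 0.95,
                    mm_mean = 3)
  expect_error(default_scenario(frac_duplicated = 0.10, divergence = div),
               "exceed 1")
})

test_that("noise-free signals are an exact function of the truth", {
  d <- make_test_design(n_tx = 15, bac_len = 3000, mt_len = 1500)
  eff <- default_effects(noise_sd = 0, gene_sd = 0, subarray_sd = 0,
                         dye_offset = 0)
  sc <- zero_scenario()
  tr <- simulate_truth(d, sheet, sc, seed = 2)
  y1 <- simulate_signals(d, tr, sheet, eff, seed = 5)
  y2 <- simulate_signals(d, tr, sheet, eff, seed = 99)
  expect_identical(y1, y2) # no randomness left
  # closed form: baseline + gc_slope * (gc - 0.44)
  expected <- eff$baseline_log2 +
    eff$gc_slope * (d$probes$gc_fraction - 0.44)
  expect_equal(unname(y1[, 1]), expected, tolerance = 1e-12)
})

test_that("copy number 2 adds exactly one log2 unit when noise is off", {
  d <- make_test_design(n_tx = 10, n_bac = 0, mt_len = 0)
  eff <- default_effects(noise_sd = 0, gene_sd = 0, subarray_sd = 0,
                         dye_offset = 0, gc_slope = 0)
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 2)
  y1 <- simulate_signals(d, tr, sheet, eff, seed = 1)
  tr$copy_number[1, ] <- 2L
  y2 <- simulate_signals(d, tr, sheet, eff, seed = 1)
  moved <- d$probes$gene_id == d$genes$gene_id[1]
  expect_equal(unname(y2[moved, ] - y1[moved, ]),
               matrix(1, sum(moved), ncol(y1)), tolerance = 1e-12)
  expect_equal(y2[!moved, ], y1[!moved, ])
  # deletion drops to the floor
  tr$copy_number[1, ] <- 0L
  y0 <- simulate_signals(d, tr, sheet, eff, seed = 1)
  expect_true(all(y0[moved, ] == eff$deletion_floor_log2))
})

test_that("one mismatch is free, two or more are penalized", {
  d <- make_test_design(n_tx = 10, n_bac = 0, mt_len = 0)
  eff <- default_effects(noise_sd = 0, gene_sd = 0, subarray_sd = 0,
                         dye_offset = 0)
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 2)
  grp <- "fabalis_Sweden"
  smp <- sheet$sample_id[geo_groups(sheet) == grp][1]
  y0 <- simulate_signals(d, tr, sheet, eff, seed = 1)[, smp]
  tr$mismatch[, grp] <- 1L
  y1 <- simulate_signals(d, tr, sheet, eff, seed = 1)[, smp]
  expect_equal(y1, y0) # single mismatch leaves hybridization intact
  tr$mismatch[, grp] <- 2L
  y2 <- simulate_signals(d, tr, sheet, eff, seed = 1)[, smp]
  expect_true(all(y2 < y1))
  # low-GC probes are more mismatch-sensitive
  pen <- y1 - y2
  low_gc <- d$probes$gc_fraction < 0.40
  if (any(low_gc) && any(!low_gc))
    expect_gt(min(pen[low_gc]), max(pen[!low_gc]) - 1e-12)
})

test_that("dye contrast and exon penalty propagate into the signals", {
  d <- make_test_design(n_tx = 120, n_bac = 0, mt_len = 0)
  eff <- default_effects(subarray_sd = 0)
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 4)
  y <- simulate_signals(d, tr, sheet, eff, seed = 9)
  cm <- colMeans(y)
  contrast <- mean(cm[sheet$dye == "Cy5"]) - mean(cm[sheet$dye == "Cy3"])
  se <- eff$noise_sd / sqrt(nrow(y) * 18)
  expect_lt(abs(contrast - eff$dye_offset), 5 * se + 0.01)
  # exon-boundary probes drop by the configured penalty
  tr2 <- tr
  tr2$exon_boundary[1:50] <- TRUE
  y2 <- simulate_signals(d, tr2, sheet, eff, seed = 9)
  expect_equal(unname(y[1:50, ] - y2[1:50, ]),
               matrix(eff$exon_penalty, 50, 36), tolerance = 1e-12)
})

test_that("signal simulation rejects truth/design mismatches", {
  d <- make_test_design(n_tx = 10, n_bac = 0, mt_len = 0)
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 2)
  d2 <- d
  d2$probes$probe_id[1] <- "rogue_probe"
  expect_error(simulate_signals(d2, tr, sheet), "missing from truth")
})

test_that("synthetic genome carries substitutions, introns, copies, deletions", {
  d <- make_test_design(n_tx = 12, n_bac = 1, bac_len = 5000, mt_len = 0)
  sheet <- littorina_sample_sheet()
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 3)
  grp <- "saxatilis_Sweden"
  tx1 <- d$genes$gene_id[d$genes$source_class == "transcript"][1:4]
  tr$copy_number[tx1[1], grp] <- 3L           # duplicated
  tr$copy_number[tx1[2], grp] <- 0L           # deleted
  p3 <- d$probes$probe_id[d$probes$gene_id == tx1[3]][2]
  tr$mismatch[p3, grp] <- 4L                  # divergent probe
  p4 <- d$probes$probe_id[d$probes$gene_id == tx1[4]][1]
  tr$exon_boundary[p4] <- TRUE                # exon-boundary probe
  genome <- simulate_genome(d, tr, grp, seed = 6)
  expect_equal(sum(startsWith(names(genome), paste0(tx1[1], "_c"))), 3L)
  expect_false(any(startsWith(names(genome), paste0(tx1[2], "_c"))))
  # divergent probe aligns with exactly 4 mismatches over its full length
  hit <- best_ungapped_match(
    d$probes$sequence[d$probes$probe_id == p3], genome)
  expect_true(hit$found)
  # the best segment keeps interior substitutions but may trim ones at the
  # probe ends, so 2-4 of the 4 planted substitutions remain visible
  expect_gte(hit$mismatches, 2L)
  expect_lte(hit$mismatches, 4L)
  expect_lt(hit$score, 60)
  expect_lt(hit$identity, 100)
  expect_identical(hit$contig_id, paste0(tx1[3], "_c1"))
  # exon-boundary probe only matches about half its length
  hit4 <- best_ungapped_match(
    d$probes$sequence[d$probes$probe_id == p4], genome)
  expect_true(hit4$found)
  expect_lt(hit4$hit_length, 45L)
  expect_gte(hit4$hit_length, 25L)
})
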