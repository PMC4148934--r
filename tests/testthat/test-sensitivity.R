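test_that("verbatim, partial and absent probes are matched as expected", {
  set.seed(20)
  ctg <- c(c1 = random_dna(3000), c2 = random_dna(1500))
  probe <- substr(ctg[["c1"]], 1001, 1060)
  hit <- best_ungapped_match(probe, ctg)
  expect_true(hit$found)
  expect_equal(hit$contig_id, "c1")
  expect_equal(hit$contig_start, 1000L) # 0-based
  expect_equal(hit$hit_length, 60L)
  expect_equal(hit$identity, 100)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$strand, "+")

  # only the first 26 nt present (synthetic exon boundary)
  ctg26 <- c(cx = paste0(random_dna(400), substr(probe, 1, 26),
                         random_dna(400)))
  h26 <- best_ungapped_match(probe, ctg26)
  expect_true(h26$found)
  expect_gte(h26$hit_length, 26L)
  expect_lt(h26$hit_length, 35L)

  # absent probe
  h0 <- best_ungapped_match(random_dna(60), c(c9 = random_dna(800)))
  expect_false(h0$found)

  expect_error(best_ungapped_match(random_dna(59), ctg), "60 nt")
})

test_that("matcher equals the brute-force all-offset oracle on toy contigs", {
  set.seed(22)
  for (rep in 1:6) {
    contigs <- c(a = random_dna(sample(500:2000, 1)),
                 b = random_dna(sample(500:2000, 1)))
    probe <- switch(1 + rep %% 3,
      substr(contigs[["a"]], 101, 160),                    # exact
      { # mutated copy: 4 scattered substitutions
        ch <- strsplit(substr(contigs[["b"]], 201, 260), "")[[1]]
        for (p in c(7, 20, 35, 52))
          ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
        paste(ch, collapse = "")
      },
      random_dna(60))                                      # likely absent
    got <- best_ungapped_match(probe, contigs)
    oracle <- brute_force_match(probe, contigs)
    if (got$found) {
      expect_equal(got$score, oracle$score)
    } else {
      # no exact 11-mer seed anywhere: verify with the exhaustive run check
      expect_lt(longest_exact_run(probe, contigs), 11L)
    }
  }
  # one larger instance at the 10-kb scale
  big <- c(big = random_dna(10000))
  pr <- substr(big[["big"]], 7001, 7060)
  expect_equal(best_ungapped_match(pr, big)$score,
               brute_force_match(pr, big)$score)
})

test_that("reverse-complementing contigs flips strand, preserves the hit", {
  set.seed(23)
  ctg <- c(c1 = random_dna(2000))
  probe <- substr(ctg[["c1"]], 501, 560)
  fwd <- best_ungapped_match(probe, ctg)
  rc_ctg <- c(c1 = paste(rev(strsplit(chartr("ACGT", "TGCA", ctg[["c1"]]),
                                      "")[[1]]), collapse = ""))
  rev <- best_ungapped_match(probe, rc_ctg)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev$hit_length, fwd$hit_length)
  expect_equal(rev$identity, fwd$identity)
  expect_equal(rev$score, fwd$score)
})

test_that("exon-boundary probes have systematically shorter hits", {
  d <- make_test_design(n_tx = 30, n_bac = 0, mt_len = 0, seed = 31)
  sheet <- littorina_sample_sheet()
  sc <- default_scenario(frac_duplicated = 0, frac_deleted_genomic = 0,
                         mt_copy = 1, exon_gene_frac = 0.3,
                         exon_probe_prob = 1, exon_bg_prob = 0)
  tr <- simulate_truth(d, sheet, sc, seed = 7)
  genome <- simulate_genome(d, tr, "saxatilis_Sweden", seed = 8)
  hits <- match_probes(d, genome)
  exon <- tr$exon_boundary[hits$probe_id]
  expect_gt(sum(exon), 10)
  expect_lt(stats::median(hits$hit_length[exon], na.rm = TRUE),
            stats::median(hits$hit_length[!exon], na.rm = TRUE))
  expect_equal(stats::median(hits$hit_length[!exon], na.rm = TRUE), 60)
  # intron insertion halves the matchable probe, echoing the observed
  # median hit length of about 26-30 nt for low-signal probes
  expect_lte(stats::median(hits$hit_length[exon], na.rm = TRUE), 34)
})

test_that("mismatch-class analysis reproduces the 0-vs-1 n.s. / 1-vs-2
           significant pattern under the default penalty model", {
  sheet <- littorina_sample_sheet()
  d <- make_test_design(n_tx = 48, tx_len = c(400, 401), n_bac = 0,
                        mt_len = 0, seed = 33)
  tr <- simulate_truth(d, sheet, zero_scenario(), seed = 9)
  grp <- "saxatilis_Sweden"
  n_probes <- nrow(d$probes)
  classes <- rep(0:5, length.out = n_probes)
  set.seed(10)
  classes <- sample(classes)
  tr$mismatch[, grp] <- classes
  eff <- default_effects(gene_sd = 0, gc_slope = 0)
  y <- simulate_signals(d, tr, sheet, eff, seed = 11)
  smp <- sheet$sample_id[geo_groups(sheet) == grp]
  probe_mean <- rowMeans(y[, smp])
  mca <- mismatch_class_analysis(probe_mean, classes)
  expect_equal(mca$table$class, 0:5)
  expect_true(all(mca$table$n >= 39))
  t01 <- mca$tests[mca$tests$class_a == 0 & mca$tests$class_b == 1, ]
  t12 <- mca$tests[mca$tests$class_a == 1 & mca$tests$class_b == 2, ]
  expect_gt(t01$p_value, 0.05)
  expect_lt(t12$p_value, 0.05)
  # means decrease beyond one mismatch
  expect_lt(mca$table$mean[3], mca$table$mean[2])
})

test_that("mismatch-class analysis handles degenerate inputs", {
  expect_warning(
    mca <- mismatch_class_analysis(c(1, 2, 1.5, 2.5, 3), c(0, 0, 1, 1, 2)),
    "excluded")
  expect_equal(mca$table$class, c(0, 1))
  # identical values in every class: p = 1 throughout
  mca2 <- mismatch_class_analysis(rep(5, 40), rep(0:3, each = 10))
  expect_true(all(mca2$tests$p_value == 1))
  # a 10-SD separation is detected at any conventional threshold
  set.seed(12)
  s <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  mca3 <- mismatch_class_analysis(s, rep(c(0, 1), each = 20))
  expect_lt(mca3$tests$p_value, 1e-10)
})

test_that("GC correlation matches a closed-form covariance oracle", {
  set.seed(24)
  gc <- runif(1000, 0.25, 0.6)
  # exact linearity -> R = 1
  res <- gc_signal_correlation(2 + 4 * gc, gc)
  expect_equal(res$r, 1, tolerance = 1e-12)

  # null covariate: small R, non-significant
  y0 <- rnorm(1000)
  res0 <- gc_signal_correlation(y0, gc)
  expect_lt(abs(res0$r), 0.1)
  expect_gt(res0$p_value, 0.001)

  # default-simulator-like signal: R positive and equal to the direct
  # covariance-formula computation on the same draws
  y <- 13 + 4 * (gc - 0.44) + rnorm(1000, sd = 0.5)
  mm <- rpois(1000, 1)
  res2 <- gc_signal_correlation(y, gc, mismatches = mm)
  manual <- sum((y - mean(y)) * (gc - mean(gc))) /
    sqrt(sum((y - mean(y))^2) * sum((gc - mean(gc))^2))
  expect_equal(res2$r[res2$covariate == "gc"], manual, tolerance = 1e-12)
  expect_gt(res2$r[res2$covariate == "gc"], 0)
  expect_lt(res2$p_value[res2$covariate == "gc"], 1e-4)

  expect_error(gc_signal_correlation(y, rep(0.4, 1000)), "constant")
  expect_error(gc_signal_correlation(c(1, 2), c(0.3, 0.4)), "three")
})
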