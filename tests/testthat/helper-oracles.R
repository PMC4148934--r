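# Independent oracles used across the suite. Implementations here are kept
# deliberately naive and separate from the package's code paths.

# Brute-force ungapped aligner: for every offset of the probe against every
# contig and strand, compute the best-scoring contiguous segment (+1 match /
# -2 mismatch) via prefix sums. Returns the best score and where it occurred.
brute_force_match <- function(probe, contigs) {
  probe <- toupper(probe)
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "",
                                       fixed = TRUE)[[1L]]), collapse = "")
  best <- list(score = -Inf, found = FALSE)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") probe else rc(probe)
    pch <- strsplit(pat, "", fixed = TRUE)[[1L]]
    plen <- length(pch)
    for (ci in seq_along(contigs)) {
      cch <- strsplit(toupper(contigs[[ci]]), "", fixed = TRUE)[[1L]]
      clen <- length(cch)
      for (o in (-plen + 1L):(clen - 1L)) {
        i0 <- max(1L, 1L - o); i1 <- min(plen, clen - o)
        if (i1 < i0) next
        idx <- i0:i1
        sc <- ifelse(pch[idx] == cch[idx + o], 1L, -2L)
        S <- cumsum(sc)
        lo <- cummin(c(0L, S[-length(S)]))
        seg <- S - lo
        score <- max(seg)
        # require at least one exact seed of length 11 within the segment
        if (score > best$score) {
          best <- list(score = score, found = TRUE, strand = strand,
                       contig = names(contigs)[ci], offset = o)
        }
      }
    }
  }
  best
}

# longest exact match run between probe and any contig window (both strands);
# used to decide whether a seed of length k can exist at all
longest_exact_run <- function(probe, contigs) {
  probe <- toupper(probe)
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "",
                                       fixed = TRUE)[[1L]]), collapse = "")
  best <- 0L
  for (pat in c(probe, rc(probe))) {
    pch <- strsplit(pat, "", fixed = TRUE)[[1L]]
    plen <- length(pch)
    for (ci in seq_along(contigs)) {
      cch <- strsplit(toupper(contigs[[ci]]), "", fixed = TRUE)[[1L]]
      clen <- length(cch)
      for (o in (-plen + 1L):(clen - 1L)) {
        i0 <- max(1L, 1L - o); i1 <- min(plen, clen - o)
        if (i1 < i0) next
        eq <- pch[i0:i1] == cch[(i0:i1) + o]
        r <- rle(eq)
        runs <- r$lengths[r$values]
        if (length(runs) > 0L) best <- max(best, max(runs))
      }
    }
  }
  best
}

# Least-squares branch lengths for a 4-taxon unrooted topology
# ((a,b),(c,d)): 5 edges. Returns residual sum of squares and edge lengths.
ls_quartet <- function(d, a, b, c_, d_) {
  # order of distances: ab, ac, ad, bc, bd, cd
  pairs <- rbind(c(a, b), c(a, c_), c(a, d_), c(b, c_), c(b, d_), c(c_, d_))
  y <- apply(pairs, 1L, function(p) d[p[1L], p[2L]])
  # edges: ea, eb, ec, ed, internal
  X <- rbind(c(1, 1, 0, 0, 0),
             c(1, 0, 1, 0, 1),
             c(1, 0, 0, 1, 1),
             c(0, 1, 1, 0, 1),
             c(0, 1, 0, 1, 1),
             c(0, 0, 1, 1, 0))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# Exhaustive 3-topology least-squares oracle for 4 taxa: returns the sister
# pair of the best-fitting topology.
nj_quartet_oracle <- function(d) {
  lab <- rownames(d)
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  rss <- vapply(tops, function(t)
    ls_quartet(d, lab[t[1]], lab[t[2]], lab[t[3]], lab[t[4]])$rss,
    numeric(1L))
  t <- tops[[which.min(rss)]]
  sort(lab[t[1:2]])
}

# random additive distance matrix from a random topology with positive
# branch lengths; returns list(tree, d)
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.5, 3))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# tip sets of every internal node of a phylo tree, as sorted label vectors
clade_tip_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  lapply(seq_len(phy$Nnode) + n_tip, function(node) {
    tips <- ape::extract.clade(phy, node)$tip.label
    sort(tips)
  })
}

# small structured design used by several tests
make_test_design <- function(n_tx = 60, tx_len = c(320, 900), n_bac = 1,
                             bac_len = 12000, mt_len = 4000, seed = 42) {
  set.seed(seed)
  tx <- stats::setNames(
    vapply(sample(tx_len[1]:tx_len[2], n_tx, TRUE), random_dna, character(1)),
    sprintf("tx%04d", seq_len(n_tx)))
  gn <- if (n_bac > 0)
    stats::setNames(vapply(rep(bac_len, n_bac), random_dna, character(1)),
                    sprintf("bac%02d", seq_len(n_bac))) else NULL
  mt <- if (mt_len > 0) c(mtgenome = random_dna(mt_len)) else NULL
  build_array_design(transcripts = tx, genomic = gn, mt = mt)
}
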