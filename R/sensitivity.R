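# Ungapped probe-to-genome matching and hybridization sensitivity analyses.
#
# The matcher is a deterministic seed-and-extend aligner: exact seeds of
# length `min_seed` on both strands anchor candidate ungapped alignments,
# each scored +1 per match / -2 per mismatch, and the best-scoring contiguous
# segment is reported. It echoes default BLASTN word behaviour but is not
# BLASTN: no gaps, no E-values.

# Score one ungapped alignment of `probe_chars` against a contig at a given
# 0-based offset (probe position i aligns to contig position offset + i).
# Returns the best-scoring contiguous segment (Kadane; ties: longer segment,
# then smaller start).
score_offset <- function(probe_chars, contig_chars, offset) {
  plen <- length(probe_chars)
  clen <- length(contig_chars)
  i0 <- max(1L, 1L - offset)
  i1 <- min(plen, clen - offset)
  if (i1 < i0) return(NULL)
  idx <- i0:i1
  is_match <- probe_chars[idx] == contig_chars[idx + offset]
  sc <- ifelse(is_match, 1L, -2L)
  best <- -Inf; best_len <- 0L; best_a <- 1L
  cur <- 0L; cur_a <- 1L
  for (t in seq_along(sc)) {
    if (cur <= 0L) { cur <- sc[t]; cur_a <- t } else cur <- cur + sc[t]
    len <- t - cur_a + 1L
    if (cur > best || (cur == best && len > best_len)) {
      best <- cur; best_len <- len; best_a <- cur_a
    }
  }
  a <- idx[best_a]; b <- a + best_len - 1L
  nmatch <- sum(is_match[best_a:(best_a + best_len - 1L)])
  list(score = best, hit_length = best_len,
       mismatches = best_len - nmatch,
       identity = 100 * nmatch / best_len,
       probe_start = a, contig_start = offset + a - 1L) # 0-based
}

# Precompute the search index for a contig set: contigs concatenated with
# N-spacers (exact seeds cannot span them), plus the vector of all k-mers of
# the concatenation for O(1)-ish seed lookup, and per-contig character
# vectors for scoring. Built once per genome and reused across probes.
build_contig_index <- function(contigs, k = 11L) {
  contigs <- as_seq_vector(contigs, "contigs")
  if (length(contigs) == 0L) stop("contigs are empty")
  spacer <- strrep("N", k + 5L)
  lens <- nchar(contigs)
  # 0-based start of each contig within the concatenated subject
  starts <- cumsum(c(0L, utils::head(lens + k + 5L, -1L)))
  concat <- toupper(paste(contigs, collapse = spacer))
  L <- nchar(concat)
  kmers <- if (L >= k) substring(concat, 1L:(L - k + 1L), k:L) else character(0)
  list(contigs = contigs,
       chars = lapply(contigs, function(s)
         strsplit(toupper(s), "", fixed = TRUE)[[1L]]),
       starts = starts, lens = lens, k = k, kmers = kmers)
}

#' Best ungapped match of a probe in a contig collection
#'
#' Seed-and-extend search of a 60-nt probe against a set of contigs on both
#' strands: every exact `min_seed`-mer of the probe anchors a candidate
#' ungapped alignment, scored +1 per match and -2 per mismatch, and the
#' best-scoring contiguous segment over all anchors is returned. With no
#' exact seed anywhere, `found` is `FALSE`. Ties are resolved towards the
#' plus strand, then the smaller contig start, then contig input order.
#'
#' @param probe A 60-nt probe sequence.
#' @param contigs FASTA path, `DNAStringSet` or named character vector.
#' @param min_seed Exact-seed length anchoring candidate alignments.
#' @param probe_id Identifier copied into the result.
#' @param index Optional precomputed search index (internal; built from
#'   `contigs` when `NULL`). [match_probes()] builds it once per genome.
#' @return One-row data frame: `probe_id`, `contig_id`, `contig_start`
#'   (0-based), `hit_length`, `identity` (percent), `mismatches`, `strand`,
#'   `score`, `found`.
#' @export
best_ungapped_match <- function(probe, contigs, min_seed = 11L,
                                probe_id = "probe", index = NULL) {
  probe <- check_sequence(probe, "probe")
  if (nchar(probe) != 60L)
    stop("probe must be exactly 60 nt, got ", nchar(probe))
  if (is.null(index)) index <- build_contig_index(contigs, k = min_seed)
  if (index$k != min_seed)
    stop("index was built with seed length ", index$k, ", not ", min_seed)
  no_hit <- data.frame(probe_id = probe_id, contig_id = NA_character_,
                       contig_start = NA_integer_, hit_length = NA_integer_,
                       identity = NA_real_, mismatches = NA_integer_,
                       strand = NA_character_, score = NA_real_,
                       found = FALSE, stringsAsFactors = FALSE)
  best <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") probe else revcomp(probe)
    pchars <- strsplit(pat, "", fixed = TRUE)[[1L]]
    n_seed <- 60L - min_seed + 1L
    seeds <- substring(pat, seq_len(n_seed), seq_len(n_seed) + min_seed - 1L)
    usable <- !grepl("N", seeds, fixed = TRUE)
    if (!any(usable)) next
    # all (subject position, pattern position) seed pairs, including
    # repeated seeds within the pattern
    pos_by_seed <- split(seq_along(seeds)[usable], seeds[usable])
    hit1 <- match(index$kmers, names(pos_by_seed))
    st1 <- which(!is.na(hit1))
    if (length(st1) == 0L) next
    reps <- lengths(pos_by_seed)[hit1[st1]]
    st <- rep(st1, reps)
    sp <- unlist(pos_by_seed[hit1[st1]], use.names = FALSE)
    ci_of <- findInterval(st, index$starts + 1L)
    offs <- st - index$starts[ci_of] - sp
    cand <- unique(data.frame(ci = ci_of, o = offs))
    for (r in seq_len(nrow(cand))) {
      ci <- cand$ci[r]
      res <- score_offset(pchars, index$chars[[ci]], cand$o[r])
      if (is.null(res)) next
      hit <- data.frame(probe_id = probe_id,
                        contig_id = names(index$contigs)[ci],
                        contig_start = res$contig_start,
                        hit_length = res$hit_length,
                        identity = res$identity,
                        mismatches = res$mismatches,
                        strand = strand, score = res$score,
                        found = TRUE, stringsAsFactors = FALSE)
      if (is.null(best) || hit$score > best$score ||
          (hit$score == best$score && best$strand == "-" &&
           hit$strand == "+") ||
          (hit$score == best$score && hit$strand == best$strand &&
           hit$contig_id == best$contig_id &&
           hit$contig_start < best$contig_start))
        best <- hit
    }
  }
  if (is.null(best)) no_hit else best
}

#' Match all probes of a design against a genome
#'
#' Applies [best_ungapped_match()] to each probe (optionally a subset) and
#' returns the stacked hit table.
#'
#' @param design An `array_design` or a probe data frame with `probe_id` and
#'   `sequence` columns.
#' @param contigs FASTA path, `DNAStringSet` or named character vector.
#' @param probe_ids Optional subset of probe ids.
#' @param min_seed Seed length, see [best_ungapped_match()].
#' @return Data frame, one row per probe.
#' @export
match_probes <- function(design, contigs, probe_ids = NULL, min_seed = 11L) {
  probes <- if (inherits(design, "array_design")) design$probes else design
  if (!is.null(probe_ids))
    probes <- probes[probes$probe_id %in% probe_ids, , drop = FALSE]
  index <- build_contig_index(contigs)
  out <- lapply(seq_len(nrow(probes)), function(i)
    best_ungapped_match(probes$sequence[i], NULL, min_seed = min_seed,
                        probe_id = probes$probe_id[i], index = index))
  do.call(rbind, out)
}

#' Signal by mismatch class, with adjacent-class t-tests
#'
#' Summarizes per-probe hybridization signals by the number of mismatches to
#' the hybridized genome (class 0, 1, 2, ...) and t-tests each pair of
#' adjacent represented classes -- the analysis that shows a single mismatch
#' in a 60-nt probe leaves hybridization intact while two or more depress it.
#' Classes with fewer than two probes are excluded with a warning.
#'
#' @param signals Numeric vector of per-probe signals.
#' @param mismatch_counts Integer vector of per-probe mismatch counts.
#' @return List of class `mismatch_classes`: `table` (class, n, mean, sd) and
#'   `tests` (class_a, class_b, t, p_value).
#' @export
mismatch_class_analysis <- function(signals, mismatch_counts) {
  if (length(signals) != length(mismatch_counts))
    stop("signals and mismatch_counts must have equal length")
  cls <- as.integer(mismatch_counts)
  tab <- table(cls)
  small <- as.integer(names(tab)[tab < 2L])
  if (length(small) > 0L) {
    warning("class(es) with fewer than 2 probes excluded: ",
            paste(small, collapse = ", "))
    keep <- !cls %in% small
    signals <- signals[keep]; cls <- cls[keep]
  }
  if (length(unique(cls)) < 2L)
    stop("need at least two mismatch classes with n >= 2")
  classes <- sort(unique(cls))
  summ <- data.frame(
    class = classes,
    n = vapply(classes, function(c) sum(cls == c), integer(1L)),
    mean = vapply(classes, function(c) mean(signals[cls == c]), numeric(1L)),
    sd = vapply(classes, function(c) stats::sd(signals[cls == c]),
                numeric(1L)))
  tests <- do.call(rbind, lapply(seq_len(length(classes) - 1L), function(i) {
    a <- signals[cls == classes[i]]
    b <- signals[cls == classes[i + 1L]]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12 &&
        abs(mean(a) - mean(b)) < 1e-12)
      return(data.frame(class_a = classes[i], class_b = classes[i + 1L],
                        t = 0, p_value = 1))
    tt <- stats::t.test(a, b)
    data.frame(class_a = classes[i], class_b = classes[i + 1L],
               t = unname(tt$statistic), p_value = tt$p.value)
  }))
  structure(list(table = summ, tests = tests), class = "mismatch_classes")
}

#' @export
print.mismatch_classes <- function(x, ...) {
  cat("Hybridization signal by mismatch class\n")
  print(x$table, row.names = FALSE)
  cat("Adjacent-class t-tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Correlation of hybridization signal with GC content (and mismatches)
#'
#' Pearson correlation (with two-sided p-value) of per-probe signal against
#' probe G+C fraction, and against the mismatch count when supplied -- the
#' probe-level sensitivity summary showing that GC content, not substitution
#' count, dominates hybridization success.
#'
#' @param signals Numeric vector of per-probe signals (n >= 3).
#' @param gc_fractions Numeric vector of probe G+C fractions.
#' @param mismatches Optional integer vector of mismatch counts.
#' @return Data frame with one row per covariate: `covariate`, `r`,
#'   `p_value`, `n`.
#' @export
gc_signal_correlation <- function(signals, gc_fractions, mismatches = NULL) {
  if (length(signals) < 3L) stop("need at least three probes")
  covs <- list(gc = gc_fractions)
  if (!is.null(mismatches)) covs$mismatches <- as.numeric(mismatches)
  out <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    if (length(v) != length(signals))
      stop("covariate '", nm, "' length mismatch")
    if (stats::sd(v) < 1e-12)
      stop("covariate '", nm, "' is constant")
    ct <- stats::cor.test(signals, v, method = "pearson")
    data.frame(covariate = nm, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(signals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
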