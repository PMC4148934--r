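#' Default simulation scenario
#'
#' The scenario fixes the genome-level ground truth the simulator emulates:
#' roughly 10% of genes duplicated with copy numbers high enough to place the
#' duplicated signal component near +2.3 centred log2 units, duplicated sets
#' ~90% shared between species, a contiguous deleted block of genomic
#' fragments shared by all groups, an elevated mitochondrial copy number, a
#' minority of transcript genes whose probes mostly straddle exon boundaries,
#' and per-group sequence divergence (mismatch rates) that mirrors the
#' Littorina phylogeny: the reference British *L. saxatilis* carries no
#' mismatches, Swedish and Spanish populations increasingly more, the sibling
#' species more still, and *L. fabalis* the most. Ecotypes within a
#' population share one genome state, so the Crab-vs-Wave contrast is an
#' exact null.
#'
#' @param frac_duplicated Fraction of genes duplicated per group.
#' @param dup_copies Integer copy numbers sampled for duplicated genes.
#' @param dup_shared Fraction of each group's duplicated set drawn from a
#'   core shared by all groups.
#' @param frac_deleted_genomic Fraction of genomic-fragment genes in the
#'   deleted block (shared across groups).
#' @param mt_copy Copy number assigned to mitochondrial fragments.
#' @param exon_gene_frac Fraction of transcript genes that are
#'   "boundary-rich" (most probes straddle an exon boundary).
#' @param exon_probe_prob Probability that a probe of a boundary-rich gene is
#'   an exon-boundary probe.
#' @param exon_bg_prob Background exon-boundary probability for other
#'   transcript probes.
#' @param divergence Data frame with columns `geo_group`, `frac_divergent`,
#'   `mm_mean`: fraction of (non-mt) genes divergent in that group and the
#'   Poisson mean mismatch count per probe of a divergent gene.
#' @param reference Geo group carrying zero mismatches (the array's source
#'   population).
#' @return A list of class `cgh_scenario`.
#' @export
default_scenario <- function(frac_duplicated = 0.10,
                             dup_copies = 4:6,
                             dup_shared = 0.90,
                             frac_deleted_genomic = 0.10,
                             mt_copy = 4L,
                             exon_gene_frac = 0.08,
                             exon_probe_prob = 0.8,
                             exon_bg_prob = 0.02,
                             divergence = NULL,
                             reference = "saxatilis_Britain") {
  if (is.null(divergence)) {
    divergence <- data.frame(
      geo_group = c("saxatilis_Britain", "saxatilis_Sweden",
                    "saxatilis_Spain", "arcana_Britain",
                    "compressa_Britain", "fabalis_Sweden"),
      frac_divergent = c(0, 0.01, 0.04, 0.06, 0.07, 0.15),
      mm_mean = c(0, 2, 3, 3, 3, 4),
      stringsAsFactors = FALSE)
  }
  sc <- list(frac_duplicated = frac_duplicated, dup_copies = dup_copies,
             dup_shared = dup_shared,
             frac_deleted_genomic = frac_deleted_genomic,
             mt_copy = as.integer(mt_copy),
             exon_gene_frac = exon_gene_frac,
             exon_probe_prob = exon_probe_prob,
             exon_bg_prob = exon_bg_prob,
             divergence = divergence, reference = reference)
  class(sc) <- "cgh_scenario"
  validate_scenario(sc)
  sc
}

#' @rdname default_scenario
#' @export
zero_scenario <- function() {
  default_scenario(frac_duplicated = 0, frac_deleted_genomic = 0,
                   mt_copy = 1L, exon_gene_frac = 0, exon_probe_prob = 0,
                   exon_bg_prob = 0,
                   divergence = data.frame(geo_group = character(),
                                           frac_divergent = numeric(),
                                           mm_mean = numeric()))
}

validate_scenario <- function(sc) {
  fr <- c(sc$frac_duplicated, sc$frac_deleted_genomic, sc$exon_gene_frac,
          sc$divergence$frac_divergent)
  if (any(fr < 0 | fr > 1))
    stop("scenario fractions must lie in [0, 1]")
  too_much <- sc$frac_duplicated + sc$divergence$frac_divergent > 1
  if (any(too_much))
    stop("duplicated + divergent fractions exceed 1 for group(s): ",
         paste(sc$divergence$geo_group[too_much], collapse = ", "))
  invisible(sc)
}

#' Default effect-size configuration for the signal model
#'
#' Parameters of the additive log2 hybridization model (see
#' [simulate_signals()]). Units are log2 intensity except where noted.
#'
#' @param baseline_log2 Single-copy mean signal (13.03, the observed gene
#'   average for the Swedish Crab group).
#' @param noise_sd Per-probe, per-sample Gaussian noise SD.
#' @param gene_sd SD of a per-gene hybridization-efficiency effect shared by
#'   all samples of a gene.
#' @param deletion_floor_log2 Signal emitted by a deleted (copy 0) gene;
#'   default `baseline_log2 - 6` (background level).
#' @param gc_slope Signal change per unit G+C fraction.
#' @param mismatch_penalty Signal drop per mismatch beyond the first (a
#'   single mismatch in a 60-nt probe leaves hybridization intact).
#' @param low_gc_boost Multiplier added to the mismatch penalty for probes
#'   with G+C below 0.40 (low-GC probes are more mismatch-sensitive).
#' @param exon_penalty Signal drop for a probe straddling an exon boundary
#'   (only part of the genomic fragment can anneal).
#' @param dye_offset Cy5-minus-Cy3 signal difference, applied symmetrically
#'   (+/- half per channel) so a dye-balanced group stays centred on the
#'   baseline.
#' @param subarray_sd SD of the per-subarray random offset.
#' @return A list of class `cgh_effects`.
#' @export
default_effects <- function(baseline_log2 = 13.03, noise_sd = 0.5,
                            gene_sd = 0.3,
                            deletion_floor_log2 = baseline_log2 - 6,
                            gc_slope = 4.0, mismatch_penalty = 0.3,
                            low_gc_boost = 1.0, exon_penalty = 2.5,
                            dye_offset = 0.3, subarray_sd = 0.2) {
  if (any(c(noise_sd, gene_sd, subarray_sd) < 0))
    stop("standard deviations must be >= 0")
  structure(list(baseline_log2 = baseline_log2, noise_sd = noise_sd,
                 gene_sd = gene_sd, deletion_floor_log2 = deletion_floor_log2,
                 gc_slope = gc_slope, mismatch_penalty = mismatch_penalty,
                 low_gc_boost = low_gc_boost, exon_penalty = exon_penalty,
                 dye_offset = dye_offset, subarray_sd = subarray_sd),
            class = "cgh_effects")
}

#' Simulate per-group genome truth for an array design
#'
#' Draws, per geographic group (species x population), the copy number of
#' every gene (0 = deleted), the mismatch count of every probe against that
#' group's genome, and a global exon-boundary flag per probe. Ecotypes within
#' a population share the group state, so ecotype contrasts are true nulls.
#' Deterministic given `seed`.
#'
#' @param design An `array_design`.
#' @param sheet Sample sheet (defines the geographic groups).
#' @param scenario A `cgh_scenario`, see [default_scenario()].
#' @param seed Integer seed.
#' @return Object of class `genome_truth`: list with `copy_number`
#'   (genes x groups integer matrix), `mismatch` (probes x groups integer
#'   matrix), `exon_boundary` (named logical per probe), `geo_groups`,
#'   `reference`, `scenario`, `seed`.
#' @export
simulate_truth <- function(design, sheet, scenario = default_scenario(),
                           seed = 1L) {
  stopifnot(inherits(design, "array_design"))
  validate_scenario(scenario)
  set.seed(seed)
  genes <- design$genes
  probes <- design$probes
  n_genes <- nrow(genes)
  grps <- unique(geo_groups(sheet))
  cn <- matrix(1L, n_genes, length(grps),
               dimnames = list(genes$gene_id, grps))

  # Duplications: one core set shared by all groups plus per-group extras.
  n_dup <- round(scenario$frac_duplicated * n_genes)
  if (n_dup > 0) {
    n_core <- round(scenario$dup_shared * n_dup)
    draw_copies <- function(n)
      scenario$dup_copies[sample.int(length(scenario$dup_copies), n,
                                     replace = TRUE)]
    core <- sample(genes$gene_id, n_core)
    cn[core, ] <- draw_copies(n_core)
    for (g in grps) {
      extra <- sample(setdiff(genes$gene_id, core), n_dup - n_core)
      if (length(extra) > 0)
        cn[extra, g] <- draw_copies(length(extra))
    }
  }

  # Mitochondrial fragments: elevated copy number in every group.
  is_mt <- genes$source_class == "mt_fragment"
  if (any(is_mt)) cn[is_mt, ] <- scenario$mt_copy

  # Deletion: one contiguous block of genomic fragments, shared by all groups.
  is_gen <- which(genes$source_class == "genomic_fragment")
  n_del <- round(scenario$frac_deleted_genomic * length(is_gen))
  if (n_del > 0) {
    start <- sample(length(is_gen) - n_del + 1L, 1L)
    cn[is_gen[start:(start + n_del - 1L)], ] <- 0L
  }

  # Exon-boundary probes: only transcript-derived probes can straddle
  # boundaries; a minority of genes is boundary-rich.
  exon <- stats::setNames(rep(FALSE, nrow(probes)), probes$probe_id)
  is_tx_gene <- genes$gene_id[genes$source_class == "transcript"]
  if (length(is_tx_gene) > 0 && scenario$exon_probe_prob > 0) {
    rich <- sample(is_tx_gene,
                   round(scenario$exon_gene_frac * length(is_tx_gene)))
    tx_probe <- probes$gene_id %in% is_tx_gene
    p <- ifelse(probes$gene_id %in% rich, scenario$exon_probe_prob,
                scenario$exon_bg_prob)
    exon[tx_probe] <- stats::rbinom(sum(tx_probe), 1L,
                                    p[tx_probe]) == 1L
  } else if (length(is_tx_gene) > 0 && scenario$exon_bg_prob > 0) {
    tx_probe <- probes$gene_id %in% is_tx_gene
    exon[tx_probe] <- stats::rbinom(sum(tx_probe), 1L,
                                    scenario$exon_bg_prob) == 1L
  }

  # Divergence: per-group divergent gene sets with Poisson mismatch counts
  # per probe; the reference group carries no mismatches.
  mm <- matrix(0L, nrow(probes), length(grps),
               dimnames = list(probes$probe_id, grps))
  div <- scenario$divergence
  divergeable <- genes$gene_id[genes$source_class != "mt_fragment"]
  for (g in grps) {
    row <- div[div$geo_group == g, ]
    if (nrow(row) == 0L || g == scenario$reference) next
    n_div <- round(row$frac_divergent * length(divergeable))
    if (n_div == 0L) next
    dset <- sample(divergeable, n_div)
    idx <- probes$gene_id %in% dset
    mm[idx, g] <- stats::rpois(sum(idx), row$mm_mean)
  }

  structure(list(copy_number = cn, mismatch = mm, exon_boundary = exon,
                 geo_groups = grps, reference = scenario$reference,
                 scenario = scenario, seed = seed),
            class = "genome_truth")
}

#' Forward-simulate probe-level log2 hybridization signals
#'
#' The additive model, per probe p of gene g, sample s in geographic group
#' G(s):
#' \deqn{y = b + \log_2 c_{gG}\; [c \ge 1;\ \mathrm{floor\ if\ } c = 0]
#'   + \beta_{gc}(\mathrm{GC}_p - 0.44)
#'   - \pi \max(0, m_{pG} - 1)(1 + \lambda I(\mathrm{GC}_p < 0.40))
#'   - \eta\, I(\mathrm{exon}_p) + \delta\, (I(\mathrm{Cy5}_s) - 1/2) + u_{sub(s)}
#'   + a_g + \epsilon_{ps}}
#' with subarray offsets \eqn{u \sim N(0, \sigma_{sub}^2)}, gene effects
#' \eqn{a \sim N(0, \sigma_{gene}^2)} and noise
#' \eqn{\epsilon \sim N(0, \sigma^2)}. With all SDs zero the signal is an
#' exact deterministic function of the truth.
#'
#' @param design An `array_design`.
#' @param truth A `genome_truth` from [simulate_truth()].
#' @param sheet Sample sheet.
#' @param effects A `cgh_effects`, see [default_effects()].
#' @param seed Integer seed.
#' @return Numeric matrix probes x samples of log2 intensities.
#' @export
simulate_signals <- function(design, truth, sheet,
                             effects = default_effects(), seed = 1L) {
  stopifnot(inherits(design, "array_design"), inherits(truth, "genome_truth"))
  probes <- design$probes
  if (!all(probes$probe_id %in% rownames(truth$mismatch)))
    stop("probe(s) missing from truth: ",
         paste(utils::head(setdiff(probes$probe_id,
                                   rownames(truth$mismatch))), collapse = ", "))
  geo <- geo_groups(sheet)
  if (!all(geo %in% truth$geo_groups))
    stop("sample group(s) missing from truth: ",
         paste(setdiff(geo, truth$geo_groups), collapse = ", "))
  set.seed(seed)
  n_p <- nrow(probes)
  n_s <- nrow(sheet)
  gene_idx <- match(probes$gene_id, design$genes$gene_id)

  sub_levels <- sort(unique(sheet$subarray))
  sub_off <- stats::rnorm(length(sub_levels), 0, effects$subarray_sd)
  gene_eff <- stats::rnorm(nrow(design$genes), 0, effects$gene_sd)
  noise <- matrix(stats::rnorm(n_p * n_s, 0, effects$noise_sd), n_p, n_s)

  cn <- truth$copy_number[gene_idx, geo, drop = FALSE]
  base <- ifelse(cn >= 1L, effects$baseline_log2 + log2(pmax(cn, 1L)),
                 effects$deletion_floor_log2)
  mm <- truth$mismatch[probes$probe_id, geo, drop = FALSE]
  gc <- probes$gc_fraction
  mm_pen <- effects$mismatch_penalty * pmax(0L, mm - 1L) *
    (1 + effects$low_gc_boost * (gc < 0.40))
  probe_term <- effects$gc_slope * (gc - 0.44) -
    effects$exon_penalty * as.numeric(truth$exon_boundary[probes$probe_id]) +
    gene_eff[gene_idx]
  sample_term <- effects$dye_offset * ((sheet$dye == "Cy5") - 0.5) +
    sub_off[match(sheet$subarray, sub_levels)]

  y <- base - mm_pen + probe_term +
    matrix(sample_term, n_p, n_s, byrow = TRUE) + noise
  dimnames(y) <- list(probes$probe_id, sheet$sample_id)
  y
}

#' Emit a synthetic genome for one geographic group
#'
#' Builds one contig per non-deleted gene, carrying that group's simulated
#' substitutions (placed within the corresponding probe windows), an inserted
#' intron at the midpoint of every exon-boundary probe, random flanking
#' sequence, and one contig copy per gene copy. Used to exercise the
#' probe-to-genome matcher the way the real analysis compares probes to a
#' draft assembly.
#'
#' @param design An `array_design` (must carry gene sequences, i.e. not one
#'   re-read from TSV).
#' @param truth A `genome_truth`.
#' @param group Geographic group whose genome to emit.
#' @param intron_length Length of inserted intron sequence (nt).
#' @param flank Random flank length added to both contig ends (nt).
#' @param seed Integer seed.
#' @return Named character vector of contig sequences (`<gene_id>_c<copy>`).
#' @export
simulate_genome <- function(design, truth, group, intron_length = 150L,
                            flank = 50L, seed = 1L) {
  stopifnot(inherits(design, "array_design"), inherits(truth, "genome_truth"))
  if (!group %in% truth$geo_groups)
    stop("unknown group: ", group)
  if (anyNA(design$genes$sequence))
    stop("design lacks gene sequences (was it re-read from TSV?)")
  set.seed(seed)
  contigs <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(design$genes))) {
    gid <- design$genes$gene_id[i]
    copies <- truth$copy_number[gid, group]
    if (copies < 1L) next
    seq_chars <- strsplit(design$genes$sequence[i], "", fixed = TRUE)[[1L]]
    pr <- design$probes[design$probes$gene_id == gid, , drop = FALSE]
    # substitutions within probe windows
    for (j in seq_len(nrow(pr))) {
      m <- truth$mismatch[pr$probe_id[j], group]
      if (m > 0L) {
        w <- nchar(pr$sequence[j])
        pos <- pr$start[j] + sample(w, min(m, w))
        for (p in pos)
          seq_chars[p] <- sample(setdiff(bases, seq_chars[p]), 1L)
      }
    }
    # introns at exon-boundary probe midpoints (insert from the right so
    # earlier coordinates stay valid)
    exon_pr <- pr[truth$exon_boundary[pr$probe_id], , drop = FALSE]
    if (nrow(exon_pr) > 0L) {
      for (j in order(exon_pr$start, decreasing = TRUE)) {
        at <- exon_pr$start[j] + nchar(exon_pr$sequence[j]) %/% 2L
        intron <- strsplit(random_dna(intron_length), "", fixed = TRUE)[[1L]]
        seq_chars <- append(seq_chars, intron, after = at)
      }
    }
    body <- paste(seq_chars, collapse = "")
    for (k in seq_len(copies)) {
      contig <- paste0(random_dna(flank), body, random_dna(flank))
      contigs[sprintf("%s_c%d", gid, k)] <- contig
    }
  }
  contigs
}

#' Simulate a simple grouped testbed matrix
#'
#' Direct gene-level generator used for operating-characteristic checks of
#' the per-gene testing machinery: `n_genes` genes by `n_groups * n_per_group`
#' samples of Gaussian noise, with `effect_frac` of the genes carrying an
#' `effect_size` log2 shift in one randomly chosen group.
#'
#' @param n_genes,n_groups,n_per_group Dimensions.
#' @param effect_frac Fraction of genes with a true group effect.
#' @param effect_size Size of the shift (log2 units).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `values` (genes x samples), `groups` (factor) and
#'   `affected` (logical per gene).
#' @export
simulate_testbed <- function(n_genes = 5000L, n_groups = 3L, n_per_group = 4L,
                             effect_frac = 0.10, effect_size = 1.0,
                             noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  n_s <- n_groups * n_per_group
  groups <- factor(rep(paste0("g", seq_len(n_groups)), each = n_per_group))
  values <- matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), n_genes, n_s)
  affected <- rep(FALSE, n_genes)
  affected[sample(n_genes, round(effect_frac * n_genes))] <- TRUE
  which_grp <- sample(n_groups, n_genes, replace = TRUE)
  for (g in seq_len(n_groups)) {
    rows <- affected & which_grp == g
    cols <- which(as.integer(groups) == g)
    values[rows, cols] <- values[rows, cols] + effect_size
  }
  rownames(values) <- sprintf("gene_%05d", seq_len(n_genes))
  colnames(values) <- sprintf("s%02d", seq_len(n_s))
  list(values = values, groups = groups, affected = affected)
}
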