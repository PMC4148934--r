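#' Example end-to-end run configuration
#'
#' A complete configuration for [run_pipeline()], sized for desk-scale runs.
#' Source sequences for the array are synthesized (seeded) at run time; all
#' thresholds and effect sizes are explicit and serializable to YAML.
#'
#' @param n_transcripts Number of transcript sources.
#' @param transcript_len_range Min/max transcript length (nt).
#' @param n_genomic,genomic_len Number and length of genomic (BAC-like)
#'   source sequences.
#' @param mt_len Mitochondrial genome length (nt).
#' @param seed Master seed (mandatory for a valid config).
#' @param output_dir Output directory.
#' @param q FDR threshold for divergence tests.
#' @param n_boot Bootstrap replicates for hierarchical clustering.
#' @param n_match_probes Number of probes matched against the synthetic
#'   genome in the sensitivity stage.
#' @return A list of class `run_config`.
#' @export
example_run_config <- function(n_transcripts = 300L,
                               transcript_len_range = c(300L, 1200L),
                               n_genomic = 2L, genomic_len = 20000L,
                               mt_len = 8022L, seed = 17L,
                               output_dir = tempfile("oligocgh_run_"),
                               q = 0.05, n_boot = 100L,
                               n_match_probes = 150L) {
  structure(list(
    seed = seed,
    output_dir = output_dir,
    design = list(n_transcripts = n_transcripts,
                  transcript_len_range = transcript_len_range,
                  n_genomic = n_genomic, genomic_len = genomic_len,
                  mt_len = mt_len, fragment_len = 1000L,
                  mt_fragment_len = 500L),
    scenario = default_scenario(),
    effects = default_effects(),
    analysis = list(q = q, n_boot = n_boot,
                    n_match_probes = n_match_probes,
                    genome_group = "saxatilis_Sweden")),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scenario and effect entries present in the file override the defaults.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- example_run_config()
  for (nm in intersect(names(y), c("seed", "output_dir"))) cfg[[nm]] <- y[[nm]]
  for (sec in c("design", "analysis"))
    for (nm in names(y[[sec]])) cfg[[sec]][[nm]] <- y[[sec]][[nm]]
  if (!is.null(y$scenario))
    cfg$scenario <- do.call(default_scenario, y$scenario)
  if (!is.null(y$effects))
    cfg$effects <- do.call(default_effects, y$effects)
  if (is.null(y$seed)) cfg$seed <- NULL
  cfg
}

validate_run_config <- function(config) {
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    stop("run config must specify an integer seed")
  if (is.null(config$output_dir)) stop("run config must specify output_dir")
  validate_scenario(config$scenario)
  invisible(config)
}

#' Run the full aCGH simulation and analysis pipeline
#'
#' Executes design -> sample sheet -> truth -> signals -> normalization ->
#' copy-number classification -> divergence testing -> clustering/PCA ->
#' probe sensitivity from a single configuration and master seed, writing
#' every stage output plus a JSON manifest with MD5 checksums. Re-running
#' with the same configuration and seed reproduces identical checksums.
#' Per-stage seeds are derived from the master seed by fixed offsets.
#'
#' @param config A `run_config` (see [example_run_config()]) or a YAML path.
#' @return The manifest, invisibly (list with `parameters`, `stages`,
#'   `files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stages <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(path) files[[basename(path)]] <<- path

  # -- design -------------------------------------------------------------
  design <- stage("design", {
    set.seed(seed + 1L)
    dl <- config$design
    tx_len <- sample(dl$transcript_len_range[1L]:dl$transcript_len_range[2L],
                     dl$n_transcripts, replace = TRUE)
    tx <- stats::setNames(vapply(tx_len, random_dna, character(1L)),
                          sprintf("tx%05d", seq_len(dl$n_transcripts)))
    gn <- stats::setNames(
      vapply(rep(dl$genomic_len, dl$n_genomic), random_dna, character(1L)),
      sprintf("bac%02d", seq_len(dl$n_genomic)))
    mt <- c(mtgenome = random_dna(dl$mt_len))
    d <- build_array_design(transcripts = tx, genomic = gn, mt = mt,
                            fragment_len = dl$fragment_len,
                            mt_fragment_len = dl$mt_fragment_len)
    emit(write_array_design(d, file.path(out_dir, "design.tsv")))
    d
  })
  stages <- c(stages, "design")

  # -- sample sheet -------------------------------------------------------
  sheet <- stage("sample_sheet", {
    s <- littorina_sample_sheet()
    validate_sample_sheet(s)
    emit(write_sample_sheet(s, file.path(out_dir, "samples.csv")))
    s
  })
  stages <- c(stages, "sample_sheet")

  # -- truth --------------------------------------------------------------
  truth <- stage("truth", {
    tr <- simulate_truth(design, sheet, config$scenario, seed = seed + 2L)
    cn <- data.frame(gene_id = rownames(tr$copy_number), tr$copy_number,
                     check.names = FALSE)
    utils::write.table(cn, file.path(out_dir, "truth_copy_number.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "truth_copy_number.tsv"))
    mm <- data.frame(probe_id = rownames(tr$mismatch), tr$mismatch,
                     exon_boundary = as.integer(tr$exon_boundary),
                     check.names = FALSE)
    utils::write.table(mm, file.path(out_dir, "truth_probes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "truth_probes.tsv"))
    tr
  })
  stages <- c(stages, "truth")

  # -- signals ------------------------------------------------------------
  signals <- stage("signals", {
    y <- simulate_signals(design, truth, sheet, config$effects,
                          seed = seed + 3L)
    emit(write_signals(y, file.path(out_dir, "signals_probe.tsv")))
    y
  })
  stages <- c(stages, "signals")

  # -- normalization ------------------------------------------------------
  norm <- stage("normalize", {
    qn <- quantile_normalize(signals)
    an <- anova_normalize(signals, sheet)
    genes_qn <- summarize_genes(qn, design, method = "median")
    emit(write_signals(genes_qn, file.path(out_dir, "signals_gene.tsv")))
    list(qn = qn, an = an, genes = genes_qn)
  })
  stages <- c(stages, "normalize")

  # -- copy number --------------------------------------------------------
  cnv <- stage("copy_number", {
    species <- sheet$species
    fits <- list(); calls <- list()
    for (sp in unique(species)) {
      v <- rowMeans(norm$genes[, sheet$sample_id[species == sp],
                               drop = FALSE])
      cv <- center_signals(v)
      fit <- fit_gaussian_mixture(as.numeric(cv), k = 3L, seed = seed + 4L,
                                  n_restarts = 3L, tol = 1e-7)
      cls <- classify_copy_number(fit, stats::setNames(as.numeric(cv),
                                                       names(v)))
      fits[[sp]] <- fit; calls[[sp]] <- cls
      emit(write_copy_calls(cls, file.path(out_dir,
                                           paste0("calls_", sp, ".tsv"))))
    }
    mix <- lapply(fits, function(f)
      list(weights = f$weights, means = f$means, sds = f$sds,
           loglik = f$loglik, n_iter = f$n_iter, converged = f$converged))
    jsonlite::write_json(mix, file.path(out_dir, "mixture_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(out_dir, "mixture_fits.json"))
    high_sets <- lapply(calls, function(cl) cl$gene_id[cl$high])
    cmp <- compare_group_calls(high_sets, reference = "saxatilis")
    jsonlite::write_json(list(regions = cmp$regions,
                              overlap_pct = as.list(cmp$overlap_pct)),
                         file.path(out_dir, "high_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(out_dir, "high_overlap.json"))
    list(fits = fits, calls = calls, comparison = cmp)
  })
  stages <- c(stages, "copy_number")

  # -- divergence ---------------------------------------------------------
  diverg <- stage("divergence", {
    geo <- geo_groups(sheet)
    res <- test_per_gene(norm$genes, geo, mode = "anova")
    fdr <- bh_fdr(stats::setNames(res$p_value, res$gene_id),
                  q = config$analysis$q)
    tab <- data.frame(gene_id = res$gene_id, statistic = res$statistic,
                      p_value = res$p_value, q_value = fdr$q_value,
                      significant = fdr$significant)
    emit(write_divergence_table(tab, file.path(out_dir, "divergence.tsv")))
    pw <- pairwise_divergence_matrix(norm$genes, geo, q = config$analysis$q,
                                     reference = truth$reference)
    cm <- data.frame(group = rownames(pw$counts), pw$counts,
                     check.names = FALSE)
    utils::write.table(cm, file.path(out_dir, "pairwise_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "pairwise_counts.tsv"))
    # ecotype contrast within saxatilis: the design-level null
    sax <- sheet$species == "saxatilis"
    eres <- test_per_gene(norm$genes[, sheet$sample_id[sax], drop = FALSE],
                          sheet$ecotype[sax], mode = "ttest")
    efdr <- bh_fdr(stats::setNames(eres$p_value, eres$gene_id),
                   q = config$analysis$q)
    list(table = tab, pairwise = pw,
         n_ecotype_significant = sum(efdr$significant))
  })
  stages <- c(stages, "divergence")

  # -- clustering / PCA ---------------------------------------------------
  clust <- stage("cluster", {
    nj <- neighbor_joining(diverg$pairwise$counts)
    ape::write.tree(nj, file.path(out_dir, "nj_divergent_counts.nwk"))
    emit(file.path(out_dir, "nj_divergent_counts.nwk"))
    hb <- hclust_bootstrap(norm$genes, n_boot = config$analysis$n_boot,
                           seed = seed + 5L)
    ape::write.tree(hb$phylo, file.path(out_dir, "hclust_bootstrap.nwk"))
    emit(file.path(out_dir, "hclust_bootstrap.nwk"))
    pca_all <- pca_signals(norm$genes)
    sig_genes <- diverg$table$gene_id[diverg$table$significant]
    pca_sig <- if (length(sig_genes) >= 2L)
      pca_signals(norm$genes, genes = sig_genes) else NULL
    sc <- data.frame(sample_id = rownames(pca_all$scores),
                     pca_all$scores[, seq_len(min(5L, ncol(pca_all$scores))),
                                    drop = FALSE])
    utils::write.table(sc, file.path(out_dir, "pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "pca_scores.tsv"))
    list(nj = nj, hboot = hb, pca_all = pca_all, pca_sig = pca_sig)
  })
  stages <- c(stages, "cluster")

  # -- sensitivity --------------------------------------------------------
  sens <- stage("sensitivity", {
    grp <- config$analysis$genome_group
    genome <- simulate_genome(design, truth, grp, seed = seed + 6L)
    emit(write_fasta(genome, file.path(out_dir, "synthetic_genome.fasta")))
    set.seed(seed + 7L)
    pid <- sample(design$probes$probe_id,
                  min(config$analysis$n_match_probes, nrow(design$probes)))
    hits <- match_probes(design, genome, probe_ids = pid)
    utils::write.table(hits, file.path(out_dir, "probe_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "probe_hits.tsv"))
    grp_samples <- sheet$sample_id[geo_groups(sheet) == grp]
    probe_mean <- rowMeans(norm$qn[, grp_samples, drop = FALSE])
    mm <- truth$mismatch[names(probe_mean), grp]
    # exclude probes of genes called high (duplication masks divergence)
    high <- cnv$calls[["saxatilis"]]
    high_genes <- high$gene_id[high$high]
    keep <- !(design$probes$gene_id[match(names(probe_mean),
                                          design$probes$probe_id)] %in%
                high_genes)
    mma <- tryCatch(mismatch_class_analysis(probe_mean[keep], mm[keep]),
                    error = function(e) NULL)
    corr <- gc_signal_correlation(probe_mean[keep],
                                  design$probes$gc_fraction[
                                    match(names(probe_mean),
                                          design$probes$probe_id)][keep],
                                  mismatches = mm[keep])
    utils::write.table(corr, file.path(out_dir, "signal_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "signal_correlations.tsv"))
    list(hits = hits, mismatch_classes = mma, correlations = corr)
  })
  stages <- c(stages, "sensitivity")

  manifest <- list(
    package = "oligocgh",
    version = as.character(utils::packageVersion("oligocgh")),
    seed = seed,
    parameters = list(design = config$design,
                      scenario = unclass(config$scenario),
                      effects = unclass(config$effects),
                      analysis = config$analysis),
    stages = stages,
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
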