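#' Per-gene group tests (one-way ANOVA or two-sample t)
#'
#' Vectorized fixed-effects one-way ANOVA (F statistic) across all rows of a
#' gene-level matrix, or a two-sample t-test when exactly two groups are
#' supplied in `"ttest"` mode (equal-variance by default, Welch optional).
#' Genes with zero variance both within and between groups are flagged and
#' assigned p = 1.
#'
#' @param m Numeric matrix, genes x samples.
#' @param groups Factor (or coercible) of length `ncol(m)`; every group must
#'   have at least two samples.
#' @param mode `"anova"` or `"ttest"`.
#' @param var_equal For `"ttest"`: pooled-variance t (default) or Welch.
#' @return Data frame with `gene_id`, `statistic`, `p_value`, `constant`
#'   (zero-variance flag), and for two groups `direction` (sign of mean of
#'   first-listed group minus the second).
#' @export
test_per_gene <- function(m, groups, mode = c("anova", "ttest"),
                          var_equal = TRUE) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  groups <- factor(groups)
  if (length(groups) != ncol(m))
    stop("groups must have one entry per sample")
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop("group(s) of size < 2: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (mode == "ttest" && nlevels(groups) != 2L)
    stop("ttest mode requires exactly two groups")

  N <- ncol(m)
  k <- nlevels(groups)
  ind <- stats::model.matrix(~ 0 + groups)
  n_g <- colSums(ind)
  sums <- m %*% ind
  means <- sweep(sums, 2L, n_g, "/")
  grand <- rowMeans(m)
  ssb <- rowSums(sweep(sweep(means, 1L, grand, "-")^2, 2L, n_g, "*"))
  sst <- rowSums((m - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  constant <- ssw < 1e-12 & ssb < 1e-12

  ids <- if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else
    rownames(m)
  if (mode == "anova") {
    fstat <- (ssb / (k - 1L)) / (ssw / (N - k))
    p <- stats::pf(fstat, k - 1L, N - k, lower.tail = FALSE)
    out <- data.frame(gene_id = ids, statistic = fstat, p_value = p,
                      constant = constant, stringsAsFactors = FALSE)
  } else {
    n1 <- n_g[1L]; n2 <- n_g[2L]
    d <- means[, 1L] - means[, 2L]
    in1 <- groups == levels(groups)[1L]
    v1 <- rowSums((m[, in1, drop = FALSE] - means[, 1L])^2) / (n1 - 1L)
    v2 <- rowSums((m[, !in1, drop = FALSE] - means[, 2L])^2) / (n2 - 1L)
    if (var_equal) {
      sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
      tstat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep(n1 + n2 - 2L, nrow(m))
    } else {
      se2 <- v1 / n1 + v2 / n2
      tstat <- d / sqrt(se2)
      df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
    }
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    out <- data.frame(gene_id = ids, statistic = tstat, p_value = p,
                      constant = constant,
                      direction = sign(d), stringsAsFactors = FALSE)
  }
  out$p_value[constant] <- 1
  out$statistic[constant] <- 0
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) with significance at
#' `q_value <= q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (names kept).
#' @param q FDR threshold.
#' @return Data frame with `p_value`, `q_value`, `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (anyNA(p_values)) {
    bad <- which(is.na(p_values))
    lab <- if (!is.null(names(p_values))) names(p_values)[bad] else bad
    stop("NaN/NA p-values for: ",
         paste(utils::head(lab, 10L), collapse = ", "))
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  out <- data.frame(p_value = as.numeric(p_values), q_value = qv,
                    significant = qv <= q)
  if (!is.null(names(p_values))) out$gene_id <- names(p_values)
  out
}

#' Pairwise divergent-gene counts between groups
#'
#' For every pair of groups (or every group against a reference), tests each
#' gene and counts the genes significant after Benjamini-Hochberg correction
#' applied within that pairwise contrast. The symmetric count matrix is the
#' distance input for neighbour-joining clustering of species and
#' populations.
#'
#' @param m Gene-level matrix, genes x samples.
#' @param groups Factor of length `ncol(m)`.
#' @param q FDR threshold per contrast.
#' @param reference Optional group name; when given, per-group significant
#'   gene lists against the reference are returned in `reference_lists`.
#' @param mode,var_equal Passed to [test_per_gene()] (pairs default to the
#'   equal-variance t-test).
#' @return List of class `pairwise_divergence`: `counts` (symmetric matrix,
#'   zero diagonal), `gene_lists` (named `"A|B"`), and optionally
#'   `reference_lists` (with a `direction` sign per gene: positive means
#'   higher signal in the non-reference group... see Details).
#' @details Direction follows the first-listed group of each contrast:
#'   `direction > 0` means the first group's mean signal is higher.
#' @export
pairwise_divergence_matrix <- function(m, groups, q = 0.05, reference = NULL,
                                       mode = "ttest", var_equal = TRUE) {
  m <- as.matrix(m)
  groups <- factor(groups)
  lev <- levels(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  counts <- matrix(0L, nlevels(groups), nlevels(groups),
                   dimnames = list(lev, lev))
  gene_lists <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    sel <- groups %in% lev[c(i, j)]
    res <- test_per_gene(m[, sel, drop = FALSE], droplevels(groups[sel]),
                         mode = mode, var_equal = var_equal)
    fdr <- bh_fdr(stats::setNames(res$p_value, res$gene_id), q = q)
    sig <- res$gene_id[fdr$significant]
    counts[i, j] <- counts[j, i] <- length(sig)
    gene_lists[[paste(lev[i], lev[j], sep = "|")]] <- sig
  }
  out <- list(counts = counts, gene_lists = gene_lists, q = q)
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("unknown reference group: ", reference)
    ref_lists <- list()
    for (g in setdiff(lev, reference)) {
      sel <- groups %in% c(g, reference)
      res <- test_per_gene(m[, sel, drop = FALSE], droplevels(groups[sel]),
                           mode = mode, var_equal = var_equal)
      fdr <- bh_fdr(stats::setNames(res$p_value, res$gene_id), q = q)
      sig <- fdr$significant
      dir <- if ("direction" %in% names(res)) {
        # direction of the non-reference group relative to the reference
        flip <- levels(droplevels(groups[sel]))[1L] == reference
        if (flip) -res$direction[sig] else res$direction[sig]
      } else rep(NA_real_, sum(sig))
      ref_lists[[g]] <- data.frame(gene_id = res$gene_id[sig],
                                   direction = dir,
                                   stringsAsFactors = FALSE)
    }
    out$reference <- reference
    out$reference_lists <- ref_lists
  }
  class(out) <- "pairwise_divergence"
  out
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat("Pairwise divergent-gene counts (q =", x$q, ")\n")
  print(x$counts)
  if (!is.null(x$reference))
    cat("Against reference", x$reference, ":",
        paste(sprintf("%s = %d", names(x$reference_lists),
                      vapply(x$reference_lists, nrow, integer(1L))),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write a divergence table as TSV
#'
#' @param res Result of [test_per_gene()] merged with [bh_fdr()] output.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_divergence_table <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
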