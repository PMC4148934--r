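#' Quantile normalization of a signal matrix
#'
#' Forces every sample (column) onto the common distribution of across-sample
#' mean order statistics, the quantile step of RMA. Ties within a sample
#' receive the mean of the tied target values. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix, features x samples.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("signal matrix contains missing values")
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' ANOVA normalization: residuals after dye and subarray effects
#'
#' Fits the global nuisance model `signal ~ dye + subarray` over all
#' observations and returns its residuals, removing the systematic Cy3/Cy5
#' offset and per-subarray intensity differences while preserving the
#' per-feature biological structure. Because dye and subarray are constant
#' within a sample, the fit reduces to a per-sample additive adjustment; the
#' residuals sum to zero within every dye level and every subarray to
#' machine precision. Subarray is fitted as a fixed effect: with two samples
#' per subarray the fixed-effect residuals coincide with the shrinkage-free
#' limit of the random-effect formulation and keep the operation exactly
#' testable.
#'
#' @param m Numeric matrix, features x samples (columns named by sample id).
#' @param sheet Sample sheet covering all columns of `m`.
#' @return Matrix of residuals, same dimensions and dimnames as `m`.
#' @export
anova_normalize <- function(m, sheet) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("signal matrix contains missing values")
  idx <- match(colnames(m), sheet$sample_id)
  if (anyNA(idx))
    stop("sample sheet does not cover sample(s): ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  sheet <- sheet[idx, , drop = FALSE]
  dye <- factor(sheet$dye)
  sub <- factor(sheet$subarray)
  if (nlevels(dye) < 2L)
    stop("need both dye levels for ANOVA normalization")
  single_dye <- tapply(as.character(dye), sub,
                       function(d) length(unique(d)) == 1L)
  if (all(single_dye) && nlevels(sub) > 1L)
    stop("dye is confounded with subarray: every subarray is single-dye")
  # every sample contributes nrow(m) equally-weighted observations, so the
  # global OLS fit equals the fit to per-sample means
  X <- stats::model.matrix(~ dye + sub)
  fit <- stats::lm.fit(X, colMeans(m))
  res <- sweep(m, 2L, fit$fitted.values)
  dimnames(res) <- dimnames(m)
  res
}

#' Summarize probe-level signals to gene level
#'
#' One value per gene per sample: the median (default; robust against a
#' single exon-boundary probe) or mean of the gene's probes.
#'
#' @param m Probe-level matrix (rows named by probe id).
#' @param design `array_design` mapping probes to genes.
#' @param method `"median"` or `"mean"`.
#' @return Gene-level matrix, rows in the design's gene order.
#' @export
summarize_genes <- function(m, design, method = c("median", "mean")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  stopifnot(inherits(design, "array_design"))
  gene_of <- design$probes$gene_id[match(rownames(m), design$probes$probe_id)]
  if (anyNA(gene_of))
    stop("probe(s) without a gene in the design: ",
         paste(utils::head(rownames(m)[is.na(gene_of)]), collapse = ", "))
  gene_ids <- design$genes$gene_id[design$genes$gene_id %in% gene_of]
  gfac <- factor(gene_of, levels = gene_ids)
  if (method == "mean") {
    out <- rowsum(m, gfac, reorder = FALSE) /
      as.vector(table(gfac)[gene_ids])
    dimnames(out) <- list(gene_ids, colnames(m))
    return(out)
  }
  counts <- table(gfac)
  if (length(unique(counts)) == 1L && counts[[1L]] <= 9L) {
    # constant probes-per-gene: vectorized median via a sorting network
    k <- counts[[1L]]
    ord <- order(as.integer(gfac))
    arr <- matrix(t(m[ord, , drop = FALSE]), nrow = ncol(m) * k)
    # arr: (samples * k) x genes, probe-major blocks of ncol(m)
    probe_rows <- lapply(seq_len(k), function(j)
      arr[(j - 1L) * ncol(m) + seq_len(ncol(m)), , drop = FALSE])
    for (i in seq_len(k - 1L)) for (j in seq_len(k - i)) {
      lo <- pmin(probe_rows[[j]], probe_rows[[j + 1L]])
      hi <- pmax(probe_rows[[j]], probe_rows[[j + 1L]])
      probe_rows[[j]] <- lo; probe_rows[[j + 1L]] <- hi
    }
    med <- if (k %% 2L == 1L) probe_rows[[(k + 1L) %/% 2L]] else
      (probe_rows[[k %/% 2L]] + probe_rows[[k %/% 2L + 1L]]) / 2
    out <- t(med)
    dimnames(out) <- list(gene_ids, colnames(m))
    return(out)
  }
  idx <- split(seq_len(nrow(m)), gfac)
  out <- t(vapply(idx, function(i) apply(m[i, , drop = FALSE], 2L,
                                         stats::median),
                  numeric(ncol(m))))
  dimnames(out) <- list(gene_ids, colnames(m))
  out
}

#' Centre a signal matrix on its grand mean
#'
#' Copy-number classification works on the centred log2 scale where zero is
#' the overall signal average.
#'
#' @param m Numeric matrix or vector.
#' @return `m` minus its grand mean, with attribute `grand_mean`.
#' @export
center_signals <- function(m) {
  gm <- mean(m)
  out <- m - gm
  attr(out, "grand_mean") <- gm
  out
}

#' Write / read a signal matrix as TSV
#'
#' Rows are features (first column `feature_id`), remaining columns samples.
#'
#' @param m Numeric matrix with dimnames.
#' @param path TSV path.
#' @return The path (write) or the matrix (read).
#' @export
write_signals <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
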