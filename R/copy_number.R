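#' Classify genes into low / normal / high signal classes
#'
#' Applies the copy-number decision rules to gene-level signals given a
#' fitted three-component mixture: a gene is called **high** (candidate
#' duplication) when its value is greater than or equal to the mean minus two
#' standard deviations of the right-hand mixture component; **normal**
#' (single copy) when it lies within two standard deviations of the central
#' component's mean; and **low** (candidate deletion or exon-boundary gene)
#' when it falls below the overall mean minus two overall standard deviations
#' -- the left mixture component is too poorly defined to threshold on. All
#' boundaries are inclusive and the calls are non-exclusive: a gene near a
#' threshold may be both normal and high.
#'
#' @param fit A converged `gmm3` with 3 components (means ascending).
#' @param values Named numeric vector of gene-level signals on the same scale
#'   as the fit.
#' @param overall_mean,overall_sd Mean and SD used for the low cutoff;
#'   default to the mean and SD of `values`.
#' @return A data frame of class `copy_calls` with columns `gene_id`,
#'   `value`, `low`, `normal`, `high`; thresholds are stored in attributes
#'   `low_cutoff`, `high_cutoff`, `normal_band`.
#' @export
classify_copy_number <- function(fit, values, overall_mean = NULL,
                                 overall_sd = NULL) {
  stopifnot(inherits(fit, "gmm3"))
  if (!fit$converged)
    stop("mixture fit did not converge; refusing to classify")
  if (fit$k != 3L) stop("classification requires a 3-component fit")
  if (is.null(overall_mean)) overall_mean <- mean(values)
  if (is.null(overall_sd)) overall_sd <- stats::sd(values)
  low_cutoff <- overall_mean - 2 * overall_sd
  high_cutoff <- fit$means[3L] - 2 * fit$sds[3L]
  normal_band <- fit$means[2L] + c(-2, 2) * fit$sds[2L]
  ids <- if (is.null(names(values))) as.character(seq_along(values)) else
    names(values)
  out <- data.frame(
    gene_id = ids,
    value = as.numeric(values),
    low = as.numeric(values) < low_cutoff,
    normal = as.numeric(values) >= normal_band[1L] &
      as.numeric(values) <= normal_band[2L],
    high = as.numeric(values) >= high_cutoff,
    stringsAsFactors = FALSE)
  attr(out, "low_cutoff") <- low_cutoff
  attr(out, "high_cutoff") <- high_cutoff
  attr(out, "normal_band") <- normal_band
  class(out) <- c("copy_calls", "data.frame")
  out
}

#' @export
print.copy_calls <- function(x, ...) {
  cat("Copy-number calls for", nrow(x), "genes\n")
  cat(sprintf("  low   (< %.3f):            %d\n", attr(x, "low_cutoff"),
              sum(x$low)))
  cat(sprintf("  normal [%.3f, %.3f]:   %d\n", attr(x, "normal_band")[1L],
              attr(x, "normal_band")[2L], sum(x$normal)))
  cat(sprintf("  high  (>= %.3f):           %d\n", attr(x, "high_cutoff"),
              sum(x$high)))
  cat("  in both normal and high:", sum(x$normal & x$high), "\n")
  invisible(x)
}

#' Compare candidate gene lists between groups
#'
#' Venn-style comparison of per-group gene sets (e.g. candidate duplicated
#' genes per species): exclusive counts for every region of the Venn
#' partition, pairwise intersection counts, and percentage overlap with a
#' reference group.
#'
#' @param call_sets Named list (>= 2 elements) of character vectors of gene
#'   ids.
#' @param reference Name of the reference group (default: first).
#' @return List of class `call_comparison`: `regions` (data frame of Venn
#'   regions with counts), `pairwise` (matrix of intersection counts),
#'   `overlap_pct` (per group, `100 * |set & ref| / |ref|`), `reference`.
#' @export
compare_group_calls <- function(call_sets, reference = NULL) {
  if (!is.list(call_sets) || length(call_sets) < 2L ||
      is.null(names(call_sets)))
    stop("call_sets must be a named list of at least two gene-id vectors")
  if (is.null(reference)) reference <- names(call_sets)[1L]
  if (!reference %in% names(call_sets)) stop("unknown reference group")
  call_sets <- lapply(call_sets, unique)
  if (any(lengths(call_sets) == 0L))
    warning("empty call set(s): ",
            paste(names(call_sets)[lengths(call_sets) == 0L], collapse = ", "))
  k <- length(call_sets)
  all_ids <- unique(unlist(call_sets))
  member <- vapply(call_sets, function(s) all_ids %in% s, logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(all_ids, names(call_sets)))
  # Venn partition: one region per non-empty subset of groups.
  subsets <- lapply(seq_len(2L^k - 1L), function(code)
    as.logical(bitwAnd(code, 2L^(seq_len(k) - 1L))))
  region_name <- vapply(subsets, function(s)
    paste(names(call_sets)[s], collapse = "&"), character(1L))
  counts <- vapply(subsets, function(s) {
    if (length(all_ids) == 0L) return(0L)
    sum(apply(member, 1L, function(row) all(row == s)))
  }, integer(1L))
  regions <- data.frame(region = region_name, count = counts,
                        stringsAsFactors = FALSE)
  pairwise <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
    length(intersect(call_sets[[i]], call_sets[[j]]))))
  dimnames(pairwise) <- list(names(call_sets), names(call_sets))
  ref_n <- length(call_sets[[reference]])
  overlap_pct <- vapply(call_sets, function(s)
    if (ref_n == 0L) 0 else
      100 * length(intersect(s, call_sets[[reference]])) / ref_n,
    numeric(1L))
  structure(list(regions = regions, pairwise = pairwise,
                 overlap_pct = overlap_pct, reference = reference),
            class = "call_comparison")
}

#' @export
print.call_comparison <- function(x, ...) {
  cat("Gene-list comparison (reference:", x$reference, ")\n")
  cat("Pairwise intersection counts:\n")
  print(x$pairwise)
  cat("Overlap with reference (% of reference set):\n")
  print(round(x$overlap_pct, 1L))
  invisible(x)
}

#' Write copy-number calls as TSV
#' @param calls A `copy_calls` data frame.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_copy_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
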