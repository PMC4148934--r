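#' Neighbour-joining tree from a distance (or divergent-gene count) matrix
#'
#' Saitou-Nei agglomeration using the Studier-Keppler Q criterion, applied
#' here to the matrix of pairwise divergent-gene counts (used directly as
#' distances, untransformed -- note counts need not be metric). Negative
#' branch lengths are clamped to zero. Ties in Q are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labeled by
#' its smallest leaf label), making the tree deterministic.
#'
#' @param d Symmetric numeric matrix (zero diagonal, labels as dimnames) or a
#'   `dist` object; at least 2 labels.
#' @return An [ape] `phylo` tree (unrooted for >= 3 leaves).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two labels")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-9)) stop("distance matrix diagonal must be zero")
  labels <- rownames(d)
  if (anyDuplicated(labels)) stop("leaf labels must be unique")

  if (n == 2L) {
    nwk <- sprintf("(%s:%.15g,%s:%.15g);", labels[1L], d[1L, 2L] / 2,
                   labels[2L], d[1L, 2L] / 2)
    return(ape::read.tree(text = nwk))
  }

  # active clusters as newick sub-strings; tie-break label = smallest leaf
  sub <- labels
  key <- labels
  D <- d
  while (length(sub) > 3L) {
    m <- length(sub)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_sub <- sprintf("(%s:%.15g,%s:%.15g)", sub[i], li, sub[j], lj)
    new_key <- min(key[i], key[j])
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    sub <- c(sub[keep], new_sub)
    key <- c(key[keep], new_key)
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  ord <- order(key)
  ls <- c(l1, l2, l3)[ord]
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);", sub[ord[1L]], ls[1L],
                 sub[ord[2L]], ls[2L], sub[ord[3L]], ls[3L])
  ape::read.tree(text = nwk)
}

#' Single-linkage clustering of samples with gene bootstrap support
#'
#' Hierarchical clustering of samples on Euclidean distances with single
#' linkage, plus bipartition support obtained by resampling genes with
#' replacement `n_boot` times and recording, for each internal node of the
#' original dendrogram, the fraction of replicate dendrograms containing the
#' same sample bipartition.
#'
#' @param m Gene-level matrix, genes x samples (>= 3 samples).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed for resampling.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List of class `cgh_hboot`: `hclust`, `phylo` (the dendrogram as an
#'   `ape` tree), `support` (per internal node, in `[0, 1]`, in
#'   `phylo$node.label` order) and `n_boot`.
#' @export
hclust_bootstrap <- function(m, n_boot = 200L, seed = NULL,
                             metric = "euclidean", linkage = "single") {
  m <- as.matrix(m)
  if (ncol(m) < 3L) stop("need at least three samples")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dd <- stats::dist(t(m), method = metric)
  if (any(dd < .Machine$double.eps))
    warning("duplicate samples at distance 0; ties broken by sample order")
  hc <- stats::hclust(dd, method = linkage)
  phy <- ape::as.phylo(hc)
  boot_trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(m), nrow(m), replace = TRUE)
    hb <- stats::hclust(stats::dist(t(m[rows, , drop = FALSE]),
                                    method = metric), method = linkage)
    boot_trees[[b]] <- ape::as.phylo(hb)
  }
  class(boot_trees) <- "multiPhylo"
  cnt <- ape::prop.clades(phy, boot_trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- cnt / n_boot
  phy$node.label <- format(support, digits = 3L)
  structure(list(hclust = hc, phylo = phy, support = support,
                 n_boot = n_boot),
            class = "cgh_hboot")
}

#' @export
print.cgh_hboot <- function(x, ...) {
  cat("Single-linkage dendrogram of", length(x$hclust$order),
      "samples with", x$n_boot, "gene-bootstrap replicates\n")
  cat("bipartition support:",
      paste(format(x$support, digits = 2L), collapse = " "), "\n")
  invisible(x)
}

#' Principal component analysis of samples over genes
#'
#' PCA of the samples x genes matrix after centring and (by default)
#' unit-variance scaling of each gene, optionally restricted to a gene
#' subset (e.g. the significant genes from a divergence test). Zero-variance
#' genes are dropped with a warning before scaling.
#'
#' @param m Gene-level matrix, genes x samples (>= 2 samples).
#' @param genes Optional character vector restricting the analysis.
#' @param scale. Scale genes to unit variance (default `TRUE`).
#' @return List of class `cgh_pca`: `scores` (samples x components),
#'   `var_explained` (proportions, summing to 1), `loadings`, `sdev`.
#' @export
pca_signals <- function(m, genes = NULL, scale. = TRUE) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least two samples")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0L)
      stop("gene(s) not in matrix: ", paste(utils::head(missing), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  X <- t(m)
  v <- apply(X, 2L, stats::var)
  if (any(v < 1e-12)) {
    warning(sum(v < 1e-12), " zero-variance gene(s) dropped before scaling")
    X <- X[, v >= 1e-12, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no genes with variance left")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, var_explained = ve, loadings = pc$rotation,
                 sdev = pc$sdev),
            class = "cgh_pca")
}

#' @export
print.cgh_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "samples;",
      length(x$var_explained), "components\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 5L)),
            collapse = ", "),
      if (length(x$var_explained) > 5L) "...", "\n")
  invisible(x)
}
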