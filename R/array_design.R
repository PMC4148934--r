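#' Fragment a long sequence into consecutive pseudo-genes
#'
#' Source sequences too long to be single array targets (BAC clones, the
#' mitochondrial genome) are cut into consecutive non-overlapping fragments of
#' a fixed length, each of which is treated downstream as a "gene". A trailing
#' remainder shorter than `fragment_length` is discarded; a sequence shorter
#' than `fragment_length` yields one fragment equal to the whole sequence.
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @param fragment_length Fragment length in nt (at least 60).
#' @param parent_id Identifier of the source sequence.
#' @param source_class One of `"transcript"`, `"genomic_fragment"`,
#'   `"mt_fragment"`, `"heterologous"`, `"random_control"`.
#' @return A data frame with one row per fragment: `gene_id`, `source_class`,
#'   `parent_id`, `parent_start` (0-based), `sequence`.
#' @export
#' @examples
#' nrow(fragment_sequence(strrep("ACGT", 600), 1000, "bac1")) # 2 fragments
fragment_sequence <- function(seq, fragment_length, parent_id = "seq",
                              source_class = "genomic_fragment") {
  seq <- check_sequence(seq)
  if (!is.numeric(fragment_length) || length(fragment_length) != 1L ||
      fragment_length < 60)
    stop("fragment_length must be a single number >= 60")
  fragment_length <- as.integer(fragment_length)
  len <- nchar(seq)
  if (len < fragment_length) {
    starts <- 0L
    ends <- len
  } else {
    n <- len %/% fragment_length
    starts <- (seq_len(n) - 1L) * fragment_length
    ends <- starts + fragment_length
  }
  data.frame(
    gene_id = sprintf("%s_f%04d", parent_id, seq_along(starts)),
    source_class = source_class,
    parent_id = parent_id,
    parent_start = starts,
    sequence = substring(seq, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Select GC-targeted probes for one gene
#'
#' Standard long-oligo design: each gene is represented by `probe_count`
#' non-overlapping probes of `probe_length` nt whose GC content is as close as
#' possible to `target_gc` (the platform's hybridization optimum). The gene is
#' partitioned into `probe_count` equal bins and, within each bin, the window
#' whose GC fraction is nearest the target is selected (ties broken towards
#' the smallest start, so when every window falls below the target the most
#' GC-rich window wins). Genes shorter than `probe_count * probe_length` get
#' evenly spaced, overlapping probes with starts
#' `round(i * (len - probe_length) / (probe_count - 1))`.
#'
#' @param gene_seq Nucleotide string of the gene (length >= `probe_length`).
#' @param gene_id Gene identifier used to derive probe ids.
#' @param probe_count Number of probes per gene.
#' @param probe_length Probe length in nt.
#' @param target_gc Target G+C fraction.
#' @return Data frame with `probe_id`, `gene_id`, `start` (0-based within the
#'   gene), `sequence`, `gc_fraction`.
#' @export
design_probes <- function(gene_seq, gene_id = "gene", probe_count = 5L,
                          probe_length = 60L, target_gc = 0.44) {
  gene_seq <- check_sequence(gene_seq, "gene sequence")
  len <- nchar(gene_seq)
  if (len < probe_length)
    stop("gene '", gene_id, "' is shorter (", len,
         " nt) than the probe length (", probe_length, " nt)")
  chars <- strsplit(gene_seq, "", fixed = TRUE)[[1L]]
  cum_gc <- c(0L, cumsum(chars %in% c("G", "C")))
  window_gc <- function(start0) # vectorized, 0-based starts
    (cum_gc[start0 + probe_length + 1L] - cum_gc[start0 + 1L]) / probe_length

  if (len >= probe_count * probe_length) {
    starts <- integer(probe_count)
    for (i in seq_len(probe_count)) {
      bin_lo <- floor((i - 1L) * len / probe_count)
      bin_hi <- floor(i * len / probe_count)
      cand <- bin_lo:(bin_hi - probe_length)
      gc <- window_gc(cand)
      starts[i] <- cand[which.min(abs(gc - target_gc))]
    }
  } else {
    starts <- as.integer(round_half_up(
      (seq_len(probe_count) - 1L) * (len - probe_length) / (probe_count - 1L)))
  }
  data.frame(
    probe_id = sprintf("%s_p%d", gene_id, seq_len(probe_count)),
    gene_id = gene_id,
    start = starts,
    sequence = substring(gene_seq, starts + 1L, starts + probe_length),
    gc_fraction = window_gc(starts),
    stringsAsFactors = FALSE
  )
}

#' Build an in-silico oligonucleotide array design
#'
#' Assembles the array from up to three source collections: transcripts (one
#' gene each), genomic sequences (fragmented into `fragment_len`-nt genes) and
#' a mitochondrial genome (fragmented into `mt_fragment_len`-nt genes). Each
#' gene receives `probes_per_gene` probes via [design_probes()]. Genes shorter
#' than one probe or with more than `max_n_frac` ambiguous (`N`) bases are
#' dropped with a warning.
#'
#' @param transcripts,genomic,mt FASTA path, `DNAStringSet` or named character
#'   vector for each source collection (any may be `NULL`).
#' @param fragment_len Fragment length for genomic sources (nt).
#' @param mt_fragment_len Fragment length for the mitochondrial genome (nt).
#' @param probes_per_gene,probe_length,target_gc Probe design parameters.
#' @param max_n_frac Maximum tolerated fraction of `N` bases per gene.
#' @return An object of class `array_design`: a list with data frames `genes`
#'   (`gene_id`, `source_class`, `parent_id`, `parent_start`, `length`,
#'   `sequence`) and `probes` (see [design_probes()]), plus `probes_per_gene`.
#' @export
build_array_design <- function(transcripts = NULL, genomic = NULL, mt = NULL,
                               fragment_len = 1000L, mt_fragment_len = 500L,
                               probes_per_gene = 5L, probe_length = 60L,
                               target_gc = 0.44, max_n_frac = 0.1) {
  genes <- list()
  if (!is.null(transcripts)) {
    tx <- as_seq_vector(transcripts, "transcript")
    genes$tx <- data.frame(
      gene_id = names(tx), source_class = "transcript",
      parent_id = names(tx), parent_start = 0L,
      sequence = toupper(unname(tx)), stringsAsFactors = FALSE)
  }
  if (!is.null(genomic)) {
    gn <- as_seq_vector(genomic, "genomic")
    genes$gn <- do.call(rbind, lapply(names(gn), function(id)
      fragment_sequence(gn[[id]], fragment_len, id, "genomic_fragment")))
  }
  if (!is.null(mt)) {
    mtv <- as_seq_vector(mt, "mt")
    genes$mt <- do.call(rbind, lapply(names(mtv), function(id)
      fragment_sequence(mtv[[id]], mt_fragment_len, id, "mt_fragment")))
  }
  if (length(genes) == 0L)
    stop("no input sequences supplied")
  genes <- do.call(rbind, unname(genes))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene ids in input collections")

  short <- nchar(genes$sequence) < probe_length
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than one probe dropped")
    genes <- genes[!short, , drop = FALSE]
  }
  n_frac <- 1 - vapply(genes$sequence, function(s) {
    r <- charToRaw(s)
    mean(r != as.raw(78L)) # "N"
  }, numeric(1L), USE.NAMES = FALSE)
  high_n <- n_frac > max_n_frac
  if (any(high_n)) {
    warning(sum(high_n), " gene(s) with > ", round(100 * max_n_frac),
            "% N bases rejected")
    genes <- genes[!high_n, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("no genes left after filtering")

  probes <- do.call(rbind, Map(design_probes, genes$sequence, genes$gene_id,
                               MoreArgs = list(probe_count = probes_per_gene,
                                               probe_length = probe_length,
                                               target_gc = target_gc)))
  rownames(genes) <- rownames(probes) <- NULL
  genes$length <- nchar(genes$sequence)
  structure(list(genes = genes, probes = probes,
                 probes_per_gene = as.integer(probes_per_gene)),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat("In-silico oligonucleotide array design\n")
  cat("  genes: ", nrow(x$genes), " (",
      paste(sprintf("%s: %d", names(table(x$genes$source_class)),
                    as.integer(table(x$genes$source_class))), collapse = ", "),
      ")\n", sep = "")
  cat("  probes:", nrow(x$probes), "(", x$probes_per_gene, "per gene )\n")
  invisible(x)
}

#' Write / read an array design as TSV
#'
#' One row per probe with its gene annotation; coordinates are 0-based in the
#' file as in memory. Gene sequences are not stored, only probe sequences and
#' coordinates, so a re-read design supports all signal-level analyses.
#'
#' @param design An `array_design` object.
#' @param path Output TSV path.
#' @return `write_array_design` returns `path` invisibly; `read_array_design`
#'   returns an `array_design` (with `sequence = NA` in `genes`).
#' @export
write_array_design <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  g <- design$genes[match(design$probes$gene_id, design$genes$gene_id), ]
  out <- data.frame(
    gene_id = design$probes$gene_id,
    source_class = g$source_class,
    parent_id = g$parent_id,
    parent_start = g$parent_start,
    gene_length = g$length,
    probe_id = design$probes$probe_id,
    probe_start = design$probes$start,
    probe_sequence = design$probes$sequence,
    gc_fraction = design$probes$gc_fraction,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_array_design
#' @export
read_array_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  genes <- unique(d[, c("gene_id", "source_class", "parent_id",
                        "parent_start", "gene_length")])
  names(genes)[names(genes) == "gene_length"] <- "length"
  genes$sequence <- NA_character_
  genes <- genes[, c("gene_id", "source_class", "parent_id", "parent_start",
                     "sequence", "length")]
  probes <- data.frame(probe_id = d$probe_id, gene_id = d$gene_id,
                       start = d$probe_start, sequence = d$probe_sequence,
                       gc_fraction = d$gc_fraction, stringsAsFactors = FALSE)
  rownames(genes) <- rownames(probes) <- NULL
  structure(list(genes = genes, probes = probes,
                 probes_per_gene = as.integer(round(nrow(probes) /
                                                      nrow(genes)))),
            class = "array_design")
}
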