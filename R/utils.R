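.VALID_BASES <- c("A", "C", "G", "T", "N")

# Validate a single nucleotide string; returns it upper-cased.
check_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  if (nchar(seq) == 0L)
    stop(what, " is empty", call. = FALSE)
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, .VALID_BASES)
  if (length(bad) > 0L)
    stop("invalid symbol(s) in ", what, ": ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  seq
}

# round() in R rounds half to even; probe spacing needs conventional half-up.
round_half_up <- function(x) floor(x + 0.5)

#' Fraction of G+C bases in a sequence
#'
#' `N` (and any other ambiguity symbol) counts as non-GC; the denominator is
#' the full sequence length.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @export
#' @examples
#' gc_fraction(c("GGCC", "ATAT", "GCAN"))
gc_fraction <- function(seq) {
  vapply(toupper(seq), function(s) {
    r <- charToRaw(s)
    mean(r == as.raw(71L) | r == as.raw(67L)) # "G", "C"
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Generate a random DNA sequence with a target GC content
#'
#' @param n Sequence length in nucleotides.
#' @param gc Expected G+C fraction (bases drawn i.i.d.).
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Reverse complement of a plain character string (keeps N).
revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(seq)), "",
                     fixed = TRUE)[[1L]]), collapse = "")
}

# Coerce FASTA path / DNAStringSet / named character vector to a named
# character vector of sequences.
as_seq_vector <- function(x, what = "sequences") {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x)))
      names(x) <- sprintf("%s_%d", what, seq_along(x))
    return(toupper(x))
  }
  stop("cannot interpret ", what,
       ": supply a FASTA path, DNAStringSet or named character vector")
}

# Write a named character vector of sequences to FASTA.
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
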