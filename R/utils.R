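#' satscout: satellite DNA tandem repeats and their rDNA spacer linkage
#'
#' Tools for discovering and characterizing satellite DNA tandem repeats
#' (monomer period detection, segmentation, consensus building), decomposing
#' monomers into higher-order-repeat subunits, inferring indels between
#' repeat families, annotating 45S rDNA units and intergenic spacers (IGS),
#' classifying repeat copies as independent versus IGS-linked, profiling
#' repeats along chromosomes, and predicting PCR amplicon ladders.  A
#' seeded simulator generates synthetic genomes with planted repeats and a
#' truth manifest so the whole pipeline is testable offline.
#'
#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# Validate and normalize a nucleotide string.
.check_dna <- function(x, allow_n = FALSE, arg = "seq") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty nucleotide string", arg),
         call. = FALSE)
  x <- toupper(x)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x))
    stop(sprintf("'%s' contains characters outside %s", arg,
                 if (allow_n) "ACGTN" else "ACGT"), call. = FALSE)
  x
}

# Run code under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses the ambient stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Generate a random nucleotide sequence
#'
#' Uniform i.i.d. bases; used for simulator backgrounds and surrogate
#' references.
#'
#' @param n Sequence length in bp.
#' @param seed Optional integer seed; `NULL` draws from the ambient RNG
#'   stream.
#' @return A single character string of `n` bases.
#' @export
#' @examples
#' random_dna(10, seed = 1)
random_dna <- function(n, seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  .with_seed(seed, paste(sample(BASES, n, replace = TRUE), collapse = ""))
}

#' Reverse complement
#'
#' @param seq Nucleotide string (ACGT, N allowed).
#' @return The reverse complement as a character string.
#' @export
#' @examples
#' revcomp("AAAC")
revcomp <- function(seq) {
  seq <- .check_dna(seq, allow_n = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Split a sequence into single characters.
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# All k-mers of a sequence (character vector, position i = kmer starting at i).
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Read a FASTA file into a named character vector.
read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Write a named character vector as 60-column wrapped FASTA.
write_fasta_chr <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
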