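#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce genome input to a named character vector of replicon sequences
#'
#' Accepts a named character vector, a list of character scalars, or a
#' [Biostrings::DNAStringSet]. Sequences are upper-cased and validated to the
#' alphabet {A, C, G, T, N}.
#'
#' @param genome genome sequences in one of the accepted forms.
#' @return named character vector, one element per replicon.
#' @keywords internal
as_replicons <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.list(genome)) genome <- unlist(genome)
  if (length(genome) == 0L) stop("no sequences")
  if (is.null(names(genome)) || anyNA(names(genome)) || any(!nzchar(names(genome)))) {
    names(genome) <- paste0("replicon_", seq_along(genome))
  }
  if (anyDuplicated(names(genome))) stop("replicon ids must be unique")
  genome <- toupper(genome)
  if (any(nchar(genome) == 0L)) stop("no sequences")
  bad <- vapply(genome, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("non-ACGTN characters in record '", names(genome)[which(bad)[1]], "'")
  }
  genome
}

#' Reverse complement of a DNA string
#' @param s DNA string (character scalar).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

#' Read a (multi-)FASTA file of replicons
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_replicons(x)
}

#' Write sequences to FASTA
#' @param seqs named character vector (DNA or protein).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
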