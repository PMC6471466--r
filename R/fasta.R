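#' Read and write genomes as named character vectors
#'
#' Thin wrappers around Biostrings FASTA I/O.  Inside the package a genome
#' is simply a named character vector of upper-case chromosome sequences,
#' which keeps all downstream code in plain vectorised R.
#'
#' @param path Path to a FASTA file.
#' @return `read_genome()`: a named character vector.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_genome
#' @param genome Named character vector of sequences.
#' @return `write_genome()`: `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
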