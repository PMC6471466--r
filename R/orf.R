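STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame in the forward frames
#'
#' Scans the three forward reading frames of a spliced transcript sequence
#' for `ATG ... stop` open reading frames and returns the longest.  Ties
#' are broken by the 5'-most start, then by the lowest frame index.  Only
#' forward frames are scanned because transcript sequences are already
#' stranded (5' to 3').
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return A tibble with one row per input: `frame` (0-2), `start`, `end`
#'   (0-based half-open nucleotide coordinates on the input, stop codon
#'   included), `aa_length` (encoded residues, start codon included, stop
#'   excluded).  Sequences with no complete ORF get `aa_length` 0 and `NA`
#'   coordinates.
#' @examples
#' longest_orf("ATGAAATAG")  # encodes Met-Lys
#' @export
longest_orf <- function(seq) {
  purrr::map_dfr(toupper(seq), longest_orf_one)
}

longest_orf_one <- function(s) {
  best <- tibble::tibble(frame = NA_integer_, start = NA_integer_,
                         end = NA_integer_, aa_length = 0L)
  n <- nchar(s)
  for (f in 0:2) {
    codon_starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (f + 1L > n - 2L) next
    codons <- substring(s, codon_starts, codon_starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    if (!any(is_atg)) next
    # for each ATG, the first downstream stop in this frame
    stop_pos <- which(is_stop)
    for (a in which(is_atg)) {
      nxt <- stop_pos[stop_pos > a]
      if (length(nxt) == 0) next
      st <- nxt[1]
      aa <- st - a        # codons from ATG up to (not incl.) stop
      cand_start <- codon_starts[a] - 1L
      cand_end <- codon_starts[st] + 2L
      if (aa > best$aa_length ||
          (aa == best$aa_length && !is.na(best$start) &&
           (cand_start < best$start ||
            (cand_start == best$start && f < best$frame)))) {
        best <- tibble::tibble(frame = f, start = cand_start,
                               end = cand_end, aa_length = aa)
      }
    }
  }
  best
}
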