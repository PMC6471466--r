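#' Exon-table annotation
#'
#' `lncorth` represents gene models as a plain tibble with one row per exon
#' and columns `seq_id`, `start`, `end`, `strand`, `transcript_id`,
#' `gene_id` (plus any extra columns, e.g. `sample`).  Coordinates are
#' 0-based half-open throughout the package; conversion to and from the
#' 1-based inclusive GTF convention happens only in [read_gtf()] and
#' [write_gtf()].
#'
#' `as_annotation()` validates a data frame against the exon-table contract
#' and returns it sorted by gene, transcript and start.
#'
#' @param x A data frame with at least the six annotation columns.
#' @return A tibble sorted by `gene_id`, `transcript_id`, `start`.
#' @examples
#' ann <- tibble::tibble(
#'   seq_id = "chr1", start = c(0L, 200L), end = c(100L, 300L),
#'   strand = "+", transcript_id = "t1", gene_id = "g1"
#' )
#' as_annotation(ann)
#' @export
as_annotation <- function(x) {
  required <- c("seq_id", "start", "end", "strand", "transcript_id", "gene_id")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(dplyr::arrange(x, .data$gene_id, .data$transcript_id, .data$start))
  }
  if (any(!x$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort("exon intervals must satisfy 0 <= start < end")
  }
  x <- dplyr::arrange(x, .data$gene_id, .data$transcript_id, .data$start)
  bad <- x |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      one_seq = dplyr::n_distinct(.data$seq_id) == 1,
      one_strand = dplyr::n_distinct(.data$strand) == 1,
      disjoint = all(diff_ok(.data$start, .data$end)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$one_seq | !.data$one_strand | !.data$disjoint)
  if (nrow(bad) > 0) {
    abort(paste0(
      "transcript(s) violate the exon contract (single seq/strand, disjoint sorted exons): ",
      paste(utils::head(bad$transcript_id, 5), collapse = ", ")
    ))
  }
  x
}

# exons sorted by start must not overlap
diff_ok <- function(start, end) {
  n <- length(start)
  if (n <= 1) return(TRUE)
  start[-1] >= end[-n]
}

#' Per-transcript summaries of an exon table
#'
#' Collapses an annotation to one row per transcript with its genomic span,
#' exon count, spliced length and intron chain.  The intron chain — the
#' ordered list of (donor, acceptor) boundary pairs — is the key used by
#' [merge_transcripts()] to decide whether two assemblies describe the same
#' transcript.
#'
#' @param ann An annotation tibble (see [as_annotation()]).
#' @return A tibble with columns `transcript_id`, `gene_id`, `seq_id`,
#'   `strand`, `n_exons`, `span_start`, `span_end`, `spliced_bp`,
#'   `intron_chain` (a string, `""` for single-exon transcripts).
#' @export
transcript_summary <- function(ann) {
  ann <- as_annotation(ann)
  if (nrow(ann) == 0) {
    return(tibble::tibble(
      transcript_id = character(), gene_id = character(),
      seq_id = character(), strand = character(), n_exons = integer(),
      span_start = integer(), span_end = integer(), spliced_bp = integer(),
      intron_chain = character()
    ))
  }
  ann |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$seq_id, .data$strand) |>
    dplyr::summarise(
      n_exons = dplyr::n(),
      span_start = min(.data$start),
      span_end = max(.data$end),
      spliced_bp = sum(.data$end - .data$start),
      intron_chain = intron_chain_key(.data$start, .data$end),
      .groups = "drop"
    )
}

intron_chain_key <- function(start, end) {
  n <- length(start)
  if (n <= 1) return("")
  paste(end[-n], start[-1], sep = ":", collapse = ";")
}

#' Gene spans of an annotation
#'
#' The span of a gene is the minimal interval covering all exons of all its
#' transcripts.  Context classification ([classify_context()]) works on
#' gene spans, not exon structure.
#'
#' @inheritParams transcript_summary
#' @return A tibble with `gene_id`, `seq_id`, `strand`, `start`, `end`.
#' @export
gene_spans <- function(ann) {
  ann <- as_annotation(ann)
  if (nrow(ann) == 0) {
    return(tibble::tibble(
      gene_id = character(), seq_id = character(), strand = character(),
      start = integer(), end = integer()
    ))
  }
  ann |>
    dplyr::group_by(.data$gene_id, .data$seq_id, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
}

#' Spliced sequences of transcripts
#'
#' Extracts the mature (exon-concatenated) sequence of each transcript from
#' a genome.  Minus-strand transcripts are reverse-complemented so the
#' returned string reads 5' to 3'.
#'
#' @param ann An annotation tibble.
#' @param genome A named character vector of chromosome sequences, as
#'   returned by [read_genome()].
#' @return A named character vector, one element per transcript.
#' @export
spliced_sequences <- function(ann, genome) {
  ann <- as_annotation(ann)
  missing <- setdiff(unique(ann$seq_id), names(genome))
  if (length(missing) > 0) {
    abort(paste0("sequence(s) not in genome: ", paste(missing, collapse = ", ")))
  }
  pieces <- ann |>
    dplyr::mutate(piece = substring(genome[.data$seq_id], .data$start + 1L, .data$end))
  out <- pieces |>
    dplyr::group_by(.data$transcript_id, .data$strand) |>
    dplyr::summarise(seq = paste(.data$piece, collapse = ""), .groups = "drop") |>
    dplyr::mutate(seq = ifelse(.data$strand == "-", revcomp(.data$seq), .data$seq))
  setNames(out$seq, out$transcript_id)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the alphabet `A,C,G,T,N` (case kept upper).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
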