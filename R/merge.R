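#' Merge per-sample transcript assemblies by intron chain
#'
#' Reference-guided assemblers called on different samples of the same
#' tissue emit near-identical transcripts whose 5' and 3' termini wobble
#' with coverage.  Following the rule at the core of assembly merging
#' tools, transcripts on the same sequence and strand with an identical
#' intron chain are collapsed to a single record whose terminal exons take
#' the union span (minimum first-exon start, maximum last-exon end).
#' Single-exon transcripts collapse only on exact interval identity.
#' Internal exon boundaries are never altered.
#'
#' @param sets A list of annotation tibbles (one per sample), or a single
#'   annotation tibble carrying a `sample` column.
#' @param sample_ids Optional names for the elements of `sets`; defaults to
#'   list names or `sample_1 ...`.
#' @return An annotation tibble with one merged transcript per distinct
#'   (seq, strand, intron chain / exact interval) key, plus a `samples`
#'   column giving comma-separated provenance.  The merged transcript takes
#'   the lexicographically smallest contributing `transcript_id` and
#'   `gene_id`.
#' @export
merge_transcripts <- function(sets, sample_ids = NULL) {
  if (is.data.frame(sets)) {
    if (!"sample" %in% names(sets)) {
      sets <- dplyr::mutate(sets, sample = "sample_1")
    }
    ann <- as_annotation(sets)
  } else {
    genomes <- unique(unlist(purrr::map(sets, function(a) attr(a, "genome"))))
    if (length(genomes) > 1) {
      abort(paste0("cannot merge annotations from different genomes: ",
                   paste(genomes, collapse = ", ")))
    }
    if (is.null(sample_ids)) {
      sample_ids <- names(sets) %||% paste0("sample_", seq_along(sets))
    }
    ann <- dplyr::bind_rows(purrr::map2(sets, sample_ids, function(a, s) {
      dplyr::mutate(as_annotation(a), sample = s)
    }))
  }
  if (nrow(ann) == 0) {
    out <- empty_annotation()
    out$samples <- character()
    return(out)
  }
  info <- ann |>
    dplyr::group_by(.data$sample, .data$transcript_id) |>
    dplyr::mutate(
      .n_exons = dplyr::n(),
      .chain = intron_chain_key(.data$start, .data$end),
      .first_start = min(.data$start),
      .last_end = max(.data$end)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      .key = ifelse(
        .data$.n_exons == 1,
        paste(.data$seq_id, .data$strand, "se", .data$start, .data$end, sep = "|"),
        paste(.data$seq_id, .data$strand, .data$.chain, sep = "|")
      )
    )

  merged <- info |>
    dplyr::group_by(.data$.key) |>
    dplyr::mutate(
      .merged_tx = min(.data$transcript_id),
      .merged_gene = min(.data$gene_id),
      .min_start = min(.data$.first_start),
      .max_end = max(.data$.last_end),
      .samples = paste(sort(unique(.data$sample)), collapse = ",")
    ) |>
    dplyr::ungroup()

  # keep one representative copy of each key's exon structure, then widen termini
  rep <- merged |>
    dplyr::mutate(.combo = paste(.data$sample, .data$transcript_id, sep = "\r")) |>
    dplyr::group_by(.data$.key) |>
    dplyr::filter(.data$.combo == min(.data$.combo)) |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(
      start = ifelse(dplyr::row_number() == 1, .data$.min_start, .data$start),
      end = ifelse(dplyr::row_number() == dplyr::n(), .data$.max_end, .data$end)
    ) |>
    dplyr::ungroup()

  # distinct keys sharing a source transcript_id (e.g. single-exon
  # variants that did not collapse) get a disambiguating suffix
  rep <- rep |>
    dplyr::group_by(.data$.merged_tx) |>
    dplyr::mutate(.variant = match(.data$.key, unique(.data$.key)),
                  .n_variants = dplyr::n_distinct(.data$.key)) |>
    dplyr::ungroup() |>
    dplyr::mutate(.merged_tx = ifelse(.data$.n_variants > 1,
                                      paste0(.data$.merged_tx, ".v", .data$.variant),
                                      .data$.merged_tx))
  out <- rep |>
    dplyr::transmute(
      seq_id = .data$seq_id, start = .data$start, end = .data$end,
      strand = .data$strand,
      transcript_id = .data$.merged_tx, gene_id = .data$.merged_gene,
      samples = .data$.samples
    )
  as_annotation(out)
}
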