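#' Structural lncRNA candidate filter
#'
#' Applies the two structural rules that define the candidate pool: a
#' transcript is kept iff it has at least `min_exons` exons (single-exon
#' assemblies are unreliable) and a spliced length of at least
#' `min_length_bp` (the conventional 200 bp lower bound for long noncoding
#' RNAs, measured on exonic, not genomic, length).
#'
#' @param ann An annotation tibble.
#' @param min_length_bp Minimum spliced length in bp (default 200; a
#'   200 bp transcript passes).
#' @param min_exons Minimum exon count (default 2).
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `gene_id`, `n_exons`, `spliced_bp`, `kept` and `reason`
#'   (`NA` when kept, otherwise `single_exon` or `too_short`; a
#'   transcript failing both reports `single_exon`).  Kept and removed
#'   rows partition the input.
#' @seealso [filter_annotation()] to subset the exon table by a decision
#'   tibble.
#' @export
filter_structural <- function(ann, min_length_bp = 200, min_exons = 2) {
  stopifnot(min_length_bp >= 1, min_exons >= 1)
  tx <- transcript_summary(ann)
  tx |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_exons < min_exons ~ "single_exon",
        .data$spliced_bp < min_length_bp ~ "too_short",
        TRUE ~ NA_character_
      ),
      kept = is.na(.data$reason)
    ) |>
    dplyr::select("transcript_id", "gene_id", "n_exons", "spliced_bp",
                  "kept", "reason")
}

#' Coding-potential candidate filter
#'
#' Removes transcripts that look protein-coding, on two grounds: (a) any
#' exon overlaps an exon of an annotated protein-coding transcript on the
#' same strand (`annotation_overlap`); (b) the logistic coding-potential
#' score of the spliced sequence reaches `score_threshold`
#' (`coding_score`).  Antisense overlap with coding exons does not remove
#' a transcript here; it is reported later as genic antisense context.
#'
#' @param ann Annotation tibble of candidate transcripts.
#' @param genome Named character vector of chromosome sequences.
#' @param model A `coding_potential_model`.
#' @param coding Annotation tibble of the protein-coding reference.
#' @param score_threshold Score at or above which a transcript is called
#'   coding (default 0.5).
#' @return One row per transcript: `transcript_id`, `gene_id`, `score`,
#'   `kept`, `reason` (`annotation_overlap` takes precedence over
#'   `coding_score`).
#' @export
filter_coding_potential <- function(ann, genome, model, coding,
                                    score_threshold = 0.5) {
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  ann <- as_annotation(ann)
  tx <- transcript_summary(ann)
  seqs <- spliced_sequences(ann, genome)
  if (!all(tx$transcript_id %in% names(seqs))) {
    missing <- setdiff(tx$transcript_id, names(seqs))
    abort(paste0("no sequence for transcript(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  scores <- score_coding_potential(model, seqs[tx$transcript_id])
  overlap_ids <- sense_exon_overlap_ids(ann, coding)
  tx |>
    dplyr::mutate(
      score = unname(scores),
      reason = dplyr::case_when(
        .data$transcript_id %in% overlap_ids ~ "annotation_overlap",
        .data$score >= score_threshold ~ "coding_score",
        TRUE ~ NA_character_
      ),
      kept = is.na(.data$reason)
    ) |>
    dplyr::select("transcript_id", "gene_id", "score", "kept", "reason")
}

# transcripts with >=1 exon overlapping a coding exon on the same strand
sense_exon_overlap_ids <- function(ann, coding) {
  coding <- as_annotation(coding)
  if (nrow(coding) == 0 || nrow(ann) == 0) return(character())
  hits <- dplyr::inner_join(
    dplyr::select(ann, "transcript_id", "seq_id", "strand", "start", "end"),
    dplyr::select(coding, "seq_id", "strand", cstart = "start", cend = "end"),
    by = c("seq_id", "strand"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start < .data$cend, .data$cstart < .data$end)
  unique(hits$transcript_id)
}

#' Subset an exon table by a per-transcript decision tibble
#'
#' @param ann An annotation tibble.
#' @param decisions A tibble with `transcript_id` and logical `kept`, as
#'   returned by [filter_structural()] or [filter_coding_potential()].
#' @return The annotation rows of kept transcripts.
#' @export
filter_annotation <- function(ann, decisions) {
  dplyr::semi_join(
    as_annotation(ann),
    dplyr::filter(decisions, .data$kept),
    by = "transcript_id"
  )
}
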