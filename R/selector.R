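#' Combine differential-expression and expression evidence into the
#' candidate set
#'
#' The candidate set unions two disjoint rules over gene ids:
#'
#' * rule `de_both`: differentially expressed both between retina and
#'   native RPE and between native and cultured RPE (the union of the 4-
#'   and 8-week culture comparisons);
#' * rule `stable_responsive`: expressed in both native RPE and retina at
#'   the same level (expressed in both and *not* DE between them) but DE
#'   when the tissue is explanted and cultured.
#'
#' Because the second rule requires "not DE retina-vs-RPE" the two rules
#' are disjoint by construction, so the candidate count is the sum of the
#' rule counts.
#'
#' @param de_retina_vs_rpe Character vector of gene ids DE between retina
#'   and native RPE.
#' @param de_cult4,de_cult8 Gene ids DE between native and 4-/8-week
#'   cultured RPE.
#' @param expressed_native,expressed_retina Gene ids called expressed in
#'   native RPE and in retina.
#' @param universe Optional gene-id universe; when given, all inputs are
#'   intersected with it first.
#' @return A tibble with `gene_id`, logical `de_both` and
#'   `stable_responsive`, and `rule` (exactly one of the two labels).
#' @export
select_candidates <- function(de_retina_vs_rpe, de_cult4, de_cult8,
                              expressed_native, expressed_retina,
                              universe = NULL) {
  if (!is.null(universe)) {
    de_retina_vs_rpe <- intersect(de_retina_vs_rpe, universe)
    de_cult4 <- intersect(de_cult4, universe)
    de_cult8 <- intersect(de_cult8, universe)
    expressed_native <- intersect(expressed_native, universe)
    expressed_retina <- intersect(expressed_retina, universe)
  }
  de_cultured <- union(de_cult4, de_cult8)
  rule1 <- intersect(de_retina_vs_rpe, de_cultured)
  stable <- setdiff(intersect(expressed_native, expressed_retina),
                    de_retina_vs_rpe)
  rule2 <- intersect(stable, de_cultured)
  ids <- sort(union(rule1, rule2))
  tibble::tibble(
    gene_id = ids,
    de_both = ids %in% rule1,
    stable_responsive = ids %in% rule2,
    rule = ifelse(ids %in% rule1, "de_both", "stable_responsive")
  )
}

#' Purge candidates whose projections overlap target coding genes
#'
#' A projected candidate that lands inside an annotated protein-coding
#' transcript of the target genome — typically in a UTR — cannot be
#' certified as an independent lncRNA locus.  A candidate is moved to the
#' `overlapping` set when any of its projected exons overlaps any exon of
#' a target protein-coding transcript; by default overlap on either
#' strand disqualifies (set `same_strand_only = TRUE` for sense-only).
#' Candidates with no projected model are set aside as `unprojected`.
#'
#' @param candidate_genes Character vector of candidate gene ids.
#' @param projected_ann Target-genome annotation of projected candidate
#'   models (the `annotation` element of [build_target_annotation()]).
#' @param target_coding Annotation tibble of target protein-coding
#'   transcripts (all exons, UTRs included).
#' @param same_strand_only If `TRUE`, only sense overlap disqualifies.
#' @return A tibble with `gene_id` and `status` in
#'   `true_lncRNA` / `overlapping` / `unprojected`; the three statuses
#'   partition the candidates.
#' @export
purge_target_coding_overlap <- function(candidate_genes, projected_ann,
                                        target_coding,
                                        same_strand_only = FALSE) {
  target_coding <- as_annotation(target_coding)
  proj <- tibble::as_tibble(projected_ann) |>
    dplyr::filter(.data$gene_id %in% candidate_genes)
  by <- if (same_strand_only) c("seq_id", "strand") else "seq_id"
  hits <- dplyr::inner_join(
    dplyr::select(proj, "gene_id", "seq_id", "strand", "start", "end"),
    dplyr::select(target_coding, "seq_id", "strand", cstart = "start", cend = "end"),
    by = by, suffix = c("", ".coding"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start < .data$cend, .data$cstart < .data$end)
  overlapping <- unique(hits$gene_id)
  projected <- unique(proj$gene_id)
  tibble::tibble(gene_id = sort(unique(candidate_genes))) |>
    dplyr::mutate(status = dplyr::case_when(
      !.data$gene_id %in% projected ~ "unprojected",
      .data$gene_id %in% overlapping ~ "overlapping",
      TRUE ~ "true_lncRNA"
    ))
}

#' Conservation fraction
#'
#' The headline percentage of studied lncRNA loci that survive every
#' conservation and expression screen.
#'
#' @param conserved_count Number of conserved true lncRNAs.
#' @param studied_count Denominator: number of studied lncRNA loci.
#' @return `100 * conserved_count / studied_count`.
#' @examples
#' conservation_fraction(12, 700)  # 1.714...
#' @export
conservation_fraction <- function(conserved_count, studied_count) {
  if (length(studied_count) != 1 || studied_count <= 0) {
    abort("studied_count must be a single positive number")
  }
  if (conserved_count < 0 || conserved_count > studied_count) {
    abort("conserved_count must lie in [0, studied_count]")
  }
  100 * conserved_count / studied_count
}
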