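#' Project exons through pairwise alignment blocks
#'
#' Maps source-genome exons into the target genome by walking the columns
#' of pairwise alignment blocks.  For each exon, every alignment column
#' whose source position falls inside the exon is counted as an aligned
#' column (columns where the target row is gapped count as aligned
#' non-matches; columns where the source row is gapped are not source
#' positions and are skipped).  A column is a match when both bases are in
#' `A,C,G,T` (case-insensitive) and equal; `N` never matches.  The target
#' interval is the min/max of target positions hit.
#'
#' Blocks must not overlap on the source genome (ambiguous projection) and
#' source rows must be on the forward strand, as in standard pairwise
#' genome alignments.
#'
#' @param exons A tibble of exons with `seq_id`, `start`, `end`, `strand`
#'   and any id columns (kept in the output).
#' @param blocks A block tibble from [read_maf()].
#' @return The input columns plus `aligned_columns`, `matches`, `identity`
#'   (`NA` when no column aligns), `coverage` (aligned source bp / exon
#'   length), `tgt_seq`, `tgt_start`, `tgt_end`, `tgt_strand` (`NA` when
#'   the exon is outside all blocks), and `note` (`split` when one exon
#'   hits blocks that disagree on target sequence or strand).
#' @export
project_exons <- function(exons, blocks) {
  check_blocks(blocks)
  cols_by_seq <- block_column_tables(blocks)
  res <- purrr::map_dfr(seq_len(nrow(exons)), function(i) {
    project_exon_one(exons$seq_id[i], exons$start[i], exons$end[i], cols_by_seq)
  })
  dplyr::bind_cols(exons, res)
}

check_blocks <- function(blocks) {
  if (any(blocks$src_strand != "+")) {
    abort("source rows of alignment blocks must be on the forward strand")
  }
  by_seq <- split(blocks, blocks$src_seq)
  for (b in by_seq) {
    b <- b[order(b$src_start), ]
    if (nrow(b) > 1 && any(b$src_start[-1] < b$src_end[-nrow(b)])) {
      abort("alignment blocks overlap on the source genome; projection would be ambiguous")
    }
  }
  invisible(TRUE)
}

# per source seq: one data frame of alignment columns with source position,
# target position (NA at target gaps), match flag and block metadata
block_column_tables <- function(blocks) {
  tabs <- purrr::map(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    s <- strsplit(b$src_text, "", fixed = TRUE)[[1]]
    t <- strsplit(b$tgt_text, "", fixed = TRUE)[[1]]
    src_gap <- s == "-"
    tgt_gap <- t == "-"
    src_pos <- rep(NA_integer_, length(s))
    src_pos[!src_gap] <- b$src_start + seq_len(sum(!src_gap)) - 1L
    tgt_pos <- rep(NA_integer_, length(t))
    if (b$tgt_strand == "+") {
      tgt_pos[!tgt_gap] <- b$tgt_start + seq_len(sum(!tgt_gap)) - 1L
    } else {
      tgt_pos[!tgt_gap] <- b$tgt_end - seq_len(sum(!tgt_gap))
    }
    keep <- !src_gap
    data.frame(
      src_seq = b$src_seq,
      src_pos = src_pos[keep],
      tgt_pos = tgt_pos[keep],
      match = !tgt_gap[keep] &
        s[keep] == t[keep] & s[keep] %in% c("A", "C", "G", "T"),
      tgt_seq = b$tgt_seq,
      tgt_strand = b$tgt_strand,
      stringsAsFactors = FALSE
    )
  })
  split(dplyr::bind_rows(tabs), dplyr::bind_rows(tabs)$src_seq)
}

project_exon_one <- function(seq_id, start, end, cols_by_seq) {
  out <- tibble::tibble(
    aligned_columns = 0L, matches = 0L, identity = NA_real_, coverage = 0,
    tgt_seq = NA_character_, tgt_start = NA_integer_, tgt_end = NA_integer_,
    tgt_strand = NA_character_, note = NA_character_
  )
  cols <- cols_by_seq[[seq_id]]
  if (is.null(cols)) return(out)
  hit <- cols[cols$src_pos >= start & cols$src_pos < end, ]
  if (nrow(hit) == 0) return(out)
  out$aligned_columns <- nrow(hit)
  out$matches <- sum(hit$match)
  out$identity <- out$matches / out$aligned_columns
  out$coverage <- nrow(hit) / (end - start)
  if (dplyr::n_distinct(hit$tgt_seq) > 1 || dplyr::n_distinct(hit$tgt_strand) > 1) {
    out$note <- "split"
    return(out)
  }
  tp <- hit$tgt_pos[!is.na(hit$tgt_pos)]
  if (length(tp) > 0) {
    out$tgt_seq <- hit$tgt_seq[1]
    out$tgt_strand <- hit$tgt_strand[1]
    out$tgt_start <- min(tp)
    out$tgt_end <- max(tp) + 1L
  }
  out
}

#' Project a single exon
#'
#' Scalar convenience form of [project_exons()].
#'
#' @param seq_id,start,end Source exon interval (0-based half-open).
#' @param blocks A block tibble from [read_maf()].
#' @return A one-row tibble as described in [project_exons()].
#' @export
project_exon <- function(seq_id, start, end, blocks) {
  project_exons(
    tibble::tibble(seq_id = seq_id, start = start, end = end, strand = "+"),
    blocks
  )
}

#' Gene-level ortholog projection and calling
#'
#' Aggregates exon projections to gene level.  Gene identity is the
#' match-weighted mean over projected exons (total matches / total aligned
#' columns); gene coverage is total aligned source bp over total exonic
#' bp (distinct exon intervals per gene).  A gene is called an ortholog
#' when identity is at least `identity_threshold` (the boundary value
#' passes) and coverage at least `coverage_threshold`; genes whose exons
#' project to more than one target sequence or strand are never called
#' (`reason = "split_projection"`).
#'
#' @param ann Annotation tibble of the genes to project.
#' @param blocks Block tibble from [read_maf()].
#' @param identity_threshold Minimum gene identity for an ortholog call
#'   (default 0.60).
#' @param coverage_threshold Minimum fraction of exonic bp inside
#'   alignment blocks (default 0.5).
#' @return A list with `genes` (one row per gene: `gene_id`,
#'   `aligned_columns`, `matches`, `gene_identity`, `gene_coverage`,
#'   `tgt_seq`, `tgt_strand`, `ortholog_call`, `reason`) and `exons` (the
#'   per-exon projection tibble with `gene_id` and `transcript_id`).
#' @export
project_genes <- function(ann, blocks, identity_threshold = 0.60,
                          coverage_threshold = 0.5) {
  ann <- as_annotation(ann)
  ex <- dplyr::distinct(ann, .data$gene_id, .data$seq_id, .data$start,
                        .data$end, .data$strand)
  proj <- project_exons(ex, blocks)
  genes <- proj |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      aligned_columns = sum(.data$aligned_columns),
      matches = sum(.data$matches),
      gene_coverage = sum(.data$aligned_columns) / sum(.data$end - .data$start),
      n_tgt = dplyr::n_distinct(.data$tgt_seq[!is.na(.data$tgt_seq)]),
      n_tgt_strand = dplyr::n_distinct(.data$tgt_strand[!is.na(.data$tgt_strand)]),
      split = any(!is.na(.data$note) & .data$note == "split"),
      tgt_seq = if (dplyr::n_distinct(.data$tgt_seq[!is.na(.data$tgt_seq)]) == 1)
        .data$tgt_seq[!is.na(.data$tgt_seq)][1] else NA_character_,
      tgt_strand = if (dplyr::n_distinct(.data$tgt_strand[!is.na(.data$tgt_strand)]) == 1)
        .data$tgt_strand[!is.na(.data$tgt_strand)][1] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gene_identity = ifelse(.data$aligned_columns > 0,
                             .data$matches / .data$aligned_columns, NA_real_),
      split_projection = .data$split | .data$n_tgt > 1 | .data$n_tgt_strand > 1,
      ortholog_call = !.data$split_projection &
        !is.na(.data$gene_identity) &
        .data$gene_identity >= identity_threshold &
        .data$gene_coverage >= coverage_threshold,
      reason = dplyr::case_when(
        .data$ortholog_call ~ NA_character_,
        .data$split_projection ~ "split_projection",
        .data$aligned_columns == 0 ~ "unaligned",
        .data$gene_coverage < coverage_threshold ~ "low_coverage",
        TRUE ~ "low_identity"
      )
    ) |>
    dplyr::select("gene_id", "aligned_columns", "matches", "gene_identity",
                  "gene_coverage", "tgt_seq", "tgt_strand", "ortholog_call",
                  "reason")
  exons <- project_exons(
    dplyr::select(ann, "seq_id", "start", "end", "strand",
                  "transcript_id", "gene_id"),
    blocks
  )
  list(genes = genes, exons = exons)
}

#' Assemble projected exons into target-genome gene models
#'
#' Builds a target-genome annotation from per-exon projections: the
#' projected exons of each source transcript are sorted by target
#' coordinate and assembled into a target transcript model.  Transcripts
#' with unprojected exons are flagged `partial` (the missing exon is
#' dropped, order preserved); models shorter than `min_transcript_bp` are
#' flagged `short` but retained.  Transcripts whose exons project to mixed
#' target sequences or strands are dropped with flag `split`.
#'
#' @param exon_projections Per-exon projection tibble (the `exons` element
#'   of [project_genes()]), carrying `transcript_id` and `gene_id`.
#' @param min_transcript_bp Spliced-length flag threshold (default 200).
#' @return A list with `annotation` (target exon table with a `flag`
#'   column), `transcripts` (per-transcript tibble with `spliced_bp` and
#'   `flag`) and `summary` (one row: `n_genes`, `n_transcripts`,
#'   `n_ge_min_bp`, `max_spliced_bp`).
#' @export
build_target_annotation <- function(exon_projections, min_transcript_bp = 200) {
  pr <- exon_projections
  per_tx <- pr |>
    dplyr::group_by(.data$transcript_id, .data$gene_id) |>
    dplyr::summarise(
      n_exons = dplyr::n(),
      n_projected = sum(!is.na(.data$tgt_start)),
      n_tgt = dplyr::n_distinct(.data$tgt_seq[!is.na(.data$tgt_seq)]),
      n_strand = dplyr::n_distinct(.data$tgt_strand[!is.na(.data$tgt_strand)]),
      spliced_bp = sum(.data$tgt_end - .data$tgt_start, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$n_projected == 0 ~ "unprojected",
      .data$n_tgt > 1 | .data$n_strand > 1 ~ "split",
      .data$n_projected < .data$n_exons & .data$spliced_bp < min_transcript_bp ~ "partial;short",
      .data$n_projected < .data$n_exons ~ "partial",
      .data$spliced_bp < min_transcript_bp ~ "short",
      TRUE ~ "complete"
    ))
  usable <- per_tx$transcript_id[!per_tx$flag %in% c("unprojected", "split")]
  annotation <- pr |>
    dplyr::filter(.data$transcript_id %in% usable, !is.na(.data$tgt_start)) |>
    dplyr::transmute(
      seq_id = .data$tgt_seq, start = .data$tgt_start, end = .data$tgt_end,
      strand = .data$tgt_strand,
      transcript_id = .data$transcript_id, gene_id = .data$gene_id
    ) |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start) |>
    dplyr::left_join(dplyr::select(per_tx, "transcript_id", "flag"),
                     by = "transcript_id")
  kept <- per_tx |> dplyr::filter(!.data$flag %in% c("unprojected", "split"))
  summary <- tibble::tibble(
    n_genes = dplyr::n_distinct(kept$gene_id),
    n_transcripts = nrow(kept),
    n_ge_min_bp = sum(kept$spliced_bp >= min_transcript_bp),
    max_spliced_bp = if (nrow(kept) > 0) max(kept$spliced_bp) else 0L
  )
  list(annotation = annotation, transcripts = per_tx, summary = summary)
}
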