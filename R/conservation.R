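#' Codon-position substitution test for cryptic coding conservation
#'
#' Protein-coding sequences evolving under purifying selection accumulate
#' cross-species substitutions preferentially at third codon positions,
#' where most changes are synonymous.  This screen exploits that signal:
#' for each of the three forward frames, ungapped alignment columns are
#' assigned codon positions 1/2/3, substitution columns are counted, and a
#' one-sided exact binomial test asks whether substitutions are enriched
#' at position 3 relative to the null in which each substitution falls on
#' position 3 with probability equal to the fraction of counted columns at
#' position 3 (about 1/3).  The best (smallest-p) frame is reported with a
#' Bonferroni factor of 3 across frames; a transcript is flagged as
#' coding-conserved when the corrected p-value is below `alpha`.
#'
#' Columns containing a gap or `N` in either row are excluded from both
#' numerator and denominator, which also makes the statistic invariant to
#' which species is labelled source.  Alignments with fewer than
#' `min_columns` ungapped columns are reported untestable (`too_short`)
#' and never flagged.
#'
#' @param src_text,tgt_text Equal-length gapped alignment rows of the
#'   spliced source transcript and its projected target sequence.
#' @param alpha Significance level on the Bonferroni-corrected p-value
#'   (default 0.01).
#' @param min_columns Minimum ungapped columns to attempt the test
#'   (default 90).
#' @return A one-row tibble: `best_frame` (0-2), `n_columns`,
#'   `n_sub_total`, `n_sub_pos3` (at the best frame), `p_value` (raw, best
#'   frame), `p_corrected`, `flagged_coding`, `reason` (`NA` or
#'   `too_short`).
#' @export
codon_position_test <- function(src_text, tgt_text, alpha = 0.01,
                                min_columns = 90) {
  s <- strsplit(toupper(src_text), "", fixed = TRUE)[[1]]
  t <- strsplit(toupper(tgt_text), "", fixed = TRUE)[[1]]
  if (length(s) != length(t)) {
    abort("alignment rows have unequal length")
  }
  ok <- s %in% c("A", "C", "G", "T") & t %in% c("A", "C", "G", "T")
  s <- s[ok]
  t <- t[ok]
  n <- length(s)
  out <- tibble::tibble(
    best_frame = NA_integer_, n_columns = n, n_sub_total = 0L,
    n_sub_pos3 = 0L, p_value = 1, p_corrected = 1,
    flagged_coding = FALSE, reason = NA_character_
  )
  if (n < min_columns) {
    out$reason <- "too_short"
    return(out)
  }
  sub <- s != t
  n_sub <- sum(sub)
  out$n_sub_total <- n_sub
  if (n_sub == 0) {
    out$best_frame <- 0L
    return(out)
  }
  idx <- seq_len(n)
  best <- NULL
  for (f in 0:2) {
    pos <- ((idx - 1L + f) %% 3L) + 1L
    n3_cols <- sum(pos == 3L)
    p0 <- n3_cols / n
    k3 <- sum(sub & pos == 3L)
    # one-sided exact binomial upper tail P(X >= k3)
    p <- pbinom(k3 - 1L, n_sub, p0, lower.tail = FALSE)
    if (is.null(best) || p < best$p) {
      best <- list(frame = f, k3 = k3, p = p)
    }
  }
  out$best_frame <- best$frame
  out$n_sub_pos3 <- best$k3
  out$p_value <- best$p
  out$p_corrected <- min(3 * best$p, 1)
  out$flagged_coding <- out$p_corrected < alpha
  out
}

#' Screen many aligned transcripts for coding-like conservation
#'
#' Applies [codon_position_test()] to each row of a spliced-alignment
#' tibble (see [spliced_alignments()]).
#'
#' @param alignments A tibble with `transcript_id` (and optionally
#'   `gene_id`), `src_text`, `tgt_text`.
#' @inheritParams codon_position_test
#' @return One row per transcript: ids plus the [codon_position_test()]
#'   columns.
#' @export
codon_position_screen <- function(alignments, alpha = 0.01, min_columns = 90) {
  ids <- dplyr::select(alignments, dplyr::any_of(c("transcript_id", "gene_id")))
  res <- purrr::map_dfr(seq_len(nrow(alignments)), function(i) {
    codon_position_test(alignments$src_text[i], alignments$tgt_text[i],
                        alpha = alpha, min_columns = min_columns)
  })
  dplyr::bind_cols(ids, res)
}

#' Extract spliced pairwise alignments for transcripts
#'
#' Concatenates, exon by exon in source coordinate order, the alignment
#' columns of blocks overlapping each transcript's exons, giving a gapped
#' pairwise alignment of the spliced source transcript against its
#' projected target sequence.  Minus-strand transcripts are
#' reverse-complemented so rows read 5' to 3'.  Exons outside all blocks
#' contribute nothing; transcripts with no aligned column are omitted.
#'
#' @param ann Annotation tibble of the transcripts.
#' @param blocks Block tibble from [read_maf()].
#' @return A tibble with `transcript_id`, `gene_id`, `src_text`,
#'   `tgt_text`, `n_columns` (ungapped columns).
#' @export
spliced_alignments <- function(ann, blocks) {
  ann <- as_annotation(ann)
  check_blocks(blocks)
  cols_by_seq <- block_column_tables_full(blocks)
  tx <- transcript_summary(ann)
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    t1 <- tx[i, ]
    exons <- ann[ann$transcript_id == t1$transcript_id, ]
    cols <- cols_by_seq[[t1$seq_id]]
    if (is.null(cols)) return(NULL)
    pieces_s <- character(0)
    pieces_t <- character(0)
    for (j in seq_len(nrow(exons))) {
      hit <- cols[!is.na(cols$src_pos) &
                    cols$src_pos >= exons$start[j] & cols$src_pos < exons$end[j], ]
      if (nrow(hit) == 0) next
      pieces_s <- c(pieces_s, paste(hit$src_chr, collapse = ""))
      pieces_t <- c(pieces_t, paste(hit$tgt_chr, collapse = ""))
    }
    if (length(pieces_s) == 0) return(NULL)
    src_text <- paste(pieces_s, collapse = "")
    tgt_text <- paste(pieces_t, collapse = "")
    if (t1$strand == "-") {
      src_text <- revcomp_aln(src_text)
      tgt_text <- revcomp_aln(tgt_text)
    }
    tibble::tibble(
      transcript_id = t1$transcript_id, gene_id = t1$gene_id,
      src_text = src_text, tgt_text = tgt_text,
      n_columns = sum(strsplit(src_text, "", fixed = TRUE)[[1]] != "-" &
                        strsplit(tgt_text, "", fixed = TRUE)[[1]] != "-")
    )
  })
}

# like block_column_tables but keeps the aligned characters
block_column_tables_full <- function(blocks) {
  tabs <- purrr::map(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    s <- strsplit(b$src_text, "", fixed = TRUE)[[1]]
    t <- strsplit(b$tgt_text, "", fixed = TRUE)[[1]]
    src_gap <- s == "-"
    src_pos <- rep(NA_integer_, length(s))
    src_pos[!src_gap] <- b$src_start + seq_len(sum(!src_gap)) - 1L
    keep <- !src_gap
    data.frame(
      src_seq = b$src_seq, src_pos = src_pos[keep],
      src_chr = s[keep], tgt_chr = t[keep],
      stringsAsFactors = FALSE
    )
  })
  all <- dplyr::bind_rows(tabs)
  all <- all[order(all$src_pos), ]
  split(all, all$src_seq)
}

revcomp_aln <- function(x) {
  s <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Purge lncRNA candidates with coding-like conservation
#'
#' Runs the codon-position screen on every candidate with a spliced
#' alignment and partitions candidates into retained and removed sets.
#' Candidates without any projected alignment are untestable and retained
#' with `note = "untestable"`.
#'
#' @param ann Annotation tibble of candidate transcripts.
#' @param blocks Block tibble from [read_maf()].
#' @param alpha Significance level (default 0.01).
#' @return A list with `screen` (per-tested-transcript results),
#'   `retained` and `removed` (tibbles of `transcript_id`, `gene_id`,
#'   `note`).  `retained` and `removed` partition the input transcripts.
#' @export
purge_coding_like <- function(ann, blocks, alpha = 0.01) {
  ann <- as_annotation(ann)
  tx <- transcript_summary(ann)
  if (nrow(tx) == 0) {
    empty <- tibble::tibble(transcript_id = character(),
                            gene_id = character(), note = character())
    return(list(screen = tibble::tibble(), retained = empty, removed = empty))
  }
  aln <- spliced_alignments(ann, blocks)
  screen <- if (nrow(aln) > 0) codon_position_screen(aln, alpha = alpha) else tibble::tibble()
  flagged <- if (nrow(screen) > 0) screen$transcript_id[screen$flagged_coding] else character()
  tested <- if (nrow(screen) > 0) screen$transcript_id else character()
  status <- tx |>
    dplyr::transmute(
      transcript_id = .data$transcript_id, gene_id = .data$gene_id,
      note = dplyr::case_when(
        !.data$transcript_id %in% tested ~ "untestable",
        .data$transcript_id %in% flagged ~ "coding_conserved",
        TRUE ~ NA_character_
      )
    )
  list(
    screen = screen,
    retained = dplyr::filter(status, is.na(.data$note) | .data$note == "untestable"),
    removed = dplyr::filter(status, !is.na(.data$note) & .data$note == "coding_conserved")
  )
}
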