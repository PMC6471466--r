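#' Classify lncRNA candidates by genomic context
#'
#' Assigns each candidate transcript one of three mutually exclusive
#' classes relative to the protein-coding annotation, using gene spans
#' (minimum start to maximum end over a gene's transcripts):
#'
#' * `genic` — the candidate span lies fully within at least one coding
#'   gene span; orientation `sense`/`antisense` against that gene.
#' * `intergenic` — the candidate overlaps no coding gene span; subtyped
#'   within `window_bp` of the nearest gene as `divergent` (head-to-head),
#'   `convergent` (tail-to-tail) or `same_strand`, and `isolated` beyond
#'   the window (or when no coding gene exists on the sequence).
#' * `spanning` — partial overlap: the candidate overlaps a coding gene
#'   and extends into intergenic space (or across several genes).
#'
#' Nearest-gene ties are broken by smaller distance, then lexicographic
#' `gene_id`, so output is deterministic.
#'
#' @param candidates Annotation tibble of candidate transcripts.
#' @param coding Annotation tibble of the protein-coding reference (may be
#'   empty: everything is then `intergenic`/`isolated`).
#' @param window_bp Window for divergent/convergent subtyping of
#'   intergenic candidates (default 10000).
#' @return A tibble with one row per candidate transcript:
#'   `transcript_id`, `gene_id`, `class`, `orientation` (`sense`,
#'   `antisense` or `NA` for intergenic), `subtype` (intergenic only),
#'   `nearest_coding_gene`, `distance_bp` (0 for genic/spanning).
#' @export
classify_context <- function(candidates, coding, window_bp = 10000) {
  cand <- transcript_summary(candidates)
  genes <- gene_spans(coding)
  purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    classify_one(cand[i, ], genes, window_bp)
  })
}

classify_one <- function(c1, genes, window_bp) {
  g <- genes[genes$seq_id == c1$seq_id, ]
  out <- tibble::tibble(
    transcript_id = c1$transcript_id, gene_id = c1$gene_id,
    class = "intergenic", orientation = NA_character_,
    subtype = "isolated", nearest_coding_gene = NA_character_,
    distance_bp = NA_integer_
  )
  if (nrow(g) == 0) return(out)
  ov <- g$start < c1$span_end & c1$span_start < g$end
  if (any(ov)) {
    contained <- ov & g$start <= c1$span_start & c1$span_end <= g$end
    if (any(contained)) {
      out$class <- "genic"
      ref <- pick_reference(g[contained, ], c1)
    } else {
      out$class <- "spanning"
      ref <- pick_reference(g[ov, ], c1)
    }
    out$orientation <- ifelse(ref$strand == c1$strand, "sense", "antisense")
    out$subtype <- NA_character_
    out$nearest_coding_gene <- ref$gene_id
    out$distance_bp <- 0L
    return(out)
  }
  # intergenic: distance to nearest gene on this sequence
  dist <- pmax(g$start - c1$span_end, c1$span_start - g$end)
  ord <- order(dist, g$gene_id)
  ref <- g[ord[1], ]
  d <- dist[ord[1]]
  out$nearest_coding_gene <- ref$gene_id
  out$distance_bp <- as.integer(d)
  if (d > window_bp) {
    out$subtype <- "isolated"
    return(out)
  }
  cand_left <- c1$span_end <= ref$start
  if (c1$strand == ref$strand) {
    out$subtype <- "same_strand"
  } else if ((cand_left && c1$strand == "-" && ref$strand == "+") ||
             (!cand_left && c1$strand == "+" && ref$strand == "-")) {
    out$subtype <- "divergent"   # head-to-head: transcribed away from each other
  } else {
    out$subtype <- "convergent"  # tail-to-tail
  }
  out
}

# overlapped/containing gene of reference: largest overlap, then gene_id
pick_reference <- function(g, c1) {
  ovlen <- pmin(g$end, c1$span_end) - pmax(g$start, c1$span_start)
  g[order(-ovlen, g$gene_id)[1], ]
}

#' Classify all candidates and tally the classes
#'
#' Convenience wrapper around [classify_context()] returning the calls plus
#' a class tally.  The three classes are exhaustive and mutually
#' exclusive, so the tally always sums to the number of candidates.
#'
#' @inheritParams classify_context
#' @return A list with `calls` (the per-transcript tibble) and `tally`
#'   (tibble of `class`, `n` over `genic`, `intergenic`, `spanning`).
#' @export
classify_all <- function(candidates, coding, window_bp = 10000) {
  calls <- classify_context(candidates, coding, window_bp)
  tally <- tibble::tibble(class = c("genic", "intergenic", "spanning")) |>
    dplyr::left_join(dplyr::count(calls, .data$class), by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  list(calls = calls, tally = tally)
}
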