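# small constructors used across test files

exon_tbl <- function(starts, ends, tx = "t1", gene = tx, seq = "chr1",
                     strand = "+") {
  tibble::tibble(
    seq_id = seq, start = as.integer(starts), end = as.integer(ends),
    strand = strand, transcript_id = tx, gene_id = gene
  )
}

# a single gap-free pairwise block from two explicit rows
block_tbl <- function(src_text, tgt_text, src_start = 0L, tgt_start = 0L,
                      src_seq = "chr1", tgt_seq = "tchr1",
                      tgt_strand = "+", src_size = 10000L, tgt_size = 10000L) {
  src_len <- sum(strsplit(src_text, "")[[1]] != "-")
  tgt_len <- sum(strsplit(tgt_text, "")[[1]] != "-")
  tibble::tibble(
    block = 1L,
    src_seq = src_seq, src_start = as.integer(src_start),
    src_end = as.integer(src_start + src_len), src_strand = "+",
    src_size = as.integer(src_size),
    tgt_seq = tgt_seq, tgt_start = as.integer(tgt_start),
    tgt_end = as.integer(tgt_start + tgt_len), tgt_strand = tgt_strand,
    tgt_size = as.integer(tgt_size),
    src_text = src_text, tgt_text = tgt_text
  )
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# mutate k positions of a sequence (returns character vector of chars)
mutate_positions <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  chars
}

# brute-force genomic-context classification over gene spans
oracle_context_class <- function(span_start, span_end, seq, genes) {
  g <- genes[genes$seq_id == seq, ]
  if (nrow(g) == 0) return("intergenic")
  ov <- g$start < span_end & span_start < g$end
  if (!any(ov)) return("intergenic")
  if (any(ov & g$start <= span_start & span_end <= g$end)) return("genic")
  "spanning"
}

# brute-force per-exon projection by walking one block's columns
oracle_project_exon <- function(exon_start, exon_end, blocks) {
  aligned <- 0L; matches <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- strsplit(blocks$src_text[i], "")[[1]]
    t <- strsplit(blocks$tgt_text[i], "")[[1]]
    src_cursor <- blocks$src_start[i]
    for (j in seq_along(s)) {
      if (s[j] != "-") {
        if (src_cursor >= exon_start && src_cursor < exon_end) {
          aligned <- aligned + 1L
          if (s[j] %in% c("A", "C", "G", "T") && s[j] == t[j]) {
            matches <- matches + 1L
          }
        }
        src_cursor <- src_cursor + 1L
      }
    }
  }
  list(aligned = aligned, matches = matches,
       identity = if (aligned > 0) matches / aligned else NA_real_)
}

# hand step-up BH for small vectors
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
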