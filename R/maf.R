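#' Read pairwise alignment blocks from a MAF file
#'
#' Parses a Multiple Alignment Format file holding strictly pairwise blocks
#' (two `s` lines per `a` block: source genome first, target second).  MAF
#' start coordinates on the `-` strand count from the end of the
#' reverse-complemented sequence; these are normalised here to
#' forward-strand 0-based half-open intervals, with the original strand
#' kept in `src_strand`/`tgt_strand` and the alignment text left in
#' alignment orientation.
#'
#' @param path Path to a MAF file.
#' @return A tibble with one row per block, in file order: `block`,
#'   `src_seq`, `src_start`, `src_end`, `src_strand`, `src_size`,
#'   `tgt_seq`, `tgt_start`, `tgt_end`, `tgt_strand`, `tgt_size`,
#'   `src_text`, `tgt_text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  a_idx <- grep("^a", lines)
  if (length(a_idx) == 0) {
    return(empty_blocks())
  }
  bounds <- c(a_idx, length(lines) + 1L)
  rows <- purrr::map(seq_along(a_idx), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    s_lines <- chunk[grepl("^s\\s", chunk)]
    if (length(s_lines) != 2) {
      abort(paste0(
        "MAF block ", i, " has ", length(s_lines),
        " sequence rows; only pairwise blocks (exactly 2) are supported"
      ))
    }
    parsed <- purrr::map(s_lines, parse_maf_s_line, block = i)
    src <- parsed[[1]]
    tgt <- parsed[[2]]
    if (nchar(src$text) != nchar(tgt$text)) {
      abort(paste0("MAF block ", i, ": rows have unequal gapped lengths"))
    }
    both_gap <- gap_mask(src$text) & gap_mask(tgt$text)
    if (any(both_gap)) {
      abort(paste0("MAF block ", i, ": column gapped in both rows"))
    }
    tibble::tibble(
      block = i,
      src_seq = src$seq, src_start = src$fwd_start, src_end = src$fwd_end,
      src_strand = src$strand, src_size = src$src_size,
      tgt_seq = tgt$seq, tgt_start = tgt$fwd_start, tgt_end = tgt$fwd_end,
      tgt_strand = tgt$strand, tgt_size = tgt$src_size,
      src_text = src$text, tgt_text = tgt$text
    )
  })
  dplyr::bind_rows(rows)
}

empty_blocks <- function() {
  tibble::tibble(
    block = integer(),
    src_seq = character(), src_start = integer(), src_end = integer(),
    src_strand = character(), src_size = integer(),
    tgt_seq = character(), tgt_start = integer(), tgt_end = integer(),
    tgt_strand = character(), tgt_size = integer(),
    src_text = character(), tgt_text = character()
  )
}

parse_maf_s_line <- function(line, block) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) != 7) {
    abort(paste0("MAF block ", block, ": malformed s line (expected 7 fields)"))
  }
  start <- as.integer(f[3])
  size <- as.integer(f[4])
  strand <- f[5]
  src_size <- as.integer(f[6])
  text <- toupper(f[7])
  ungapped <- sum(!gap_mask(text))
  if (ungapped != size) {
    abort(paste0("MAF block ", block, ": row size ", size,
                 " does not match ungapped text length ", ungapped))
  }
  # MAF minus-strand starts count on the reverse strand
  fwd_start <- if (strand == "+") start else src_size - start - size
  list(
    seq = f[2], strand = strand, src_size = src_size,
    fwd_start = fwd_start, fwd_end = fwd_start + size, text = text
  )
}

gap_mask <- function(text) {
  strsplit(text, "", fixed = TRUE)[[1]] == "-"
}

#' Write pairwise alignment blocks as MAF
#'
#' Inverse of [read_maf()]: forward-strand internal intervals are converted
#' back to MAF start semantics (minus-strand starts counted on the reverse
#' strand).
#'
#' @param blocks A block tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines("a score=0", con)
    writeLines(maf_s_line(b$src_seq, b$src_start, b$src_end, b$src_strand, b$src_size, b$src_text), con)
    writeLines(maf_s_line(b$tgt_seq, b$tgt_start, b$tgt_end, b$tgt_strand, b$tgt_size, b$tgt_text), con)
    writeLines("", con)
  }
  invisible(path)
}

maf_s_line <- function(seq, fwd_start, fwd_end, strand, src_size, text) {
  size <- fwd_end - fwd_start
  start <- if (strand == "+") fwd_start else src_size - fwd_end
  paste("s", seq, start, size, strand, src_size, text)
}
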