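#' Read exon features from a GTF file
#'
#' Parses `exon` features of a GTF file (Ensembl attribute dialect:
#' `gene_id "..."; transcript_id "...";`) into the package's exon-table
#' annotation.  GTF's 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention at this boundary and nowhere else.
#'
#' @param path Path to a GTF file.
#' @return An annotation tibble (see [as_annotation()]), sorted stably by
#'   gene, transcript and start.
#' @seealso [write_gtf()] for the inverse operation.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(as_annotation(empty_annotation()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- idx[which(nf != 9)[1]]
    abort(paste0("malformed GTF line ", bad, ": expected 9 tab-separated fields, got ", nf[which(nf != 9)[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) {
    return(as_annotation(empty_annotation()))
  }
  m <- m[is_exon, , drop = FALSE]
  idx <- idx[is_exon]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    abort(paste0("malformed GTF line ", bad, ": non-numeric start/end"))
  }
  attrs <- m[, 9]
  gene_id <- gtf_attr(attrs, "gene_id")
  transcript_id <- gtf_attr(attrs, "transcript_id")
  if (anyNA(transcript_id)) {
    bad <- idx[which(is.na(transcript_id))[1]]
    abort(paste0("GTF line ", bad, ": exon feature without transcript_id attribute"))
  }
  if (anyNA(gene_id)) {
    bad <- idx[which(is.na(gene_id))[1]]
    abort(paste0("GTF line ", bad, ": exon feature without gene_id attribute"))
  }
  as_annotation(tibble::tibble(
    seq_id = m[, 1],
    start = start - 1L,   # GTF is 1-based inclusive
    end = end,
    strand = m[, 7],
    transcript_id = transcript_id,
    gene_id = gene_id
  ))
}

gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))
  m[, 2]
}

empty_annotation <- function() {
  tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), transcript_id = character(), gene_id = character()
  )
}

#' Write an annotation as GTF
#'
#' Emits one `exon` line per row, converting back to GTF's 1-based
#' inclusive coordinates.  `read_gtf(write_gtf(ann))` returns `ann` exactly
#' (up to column classes of extra columns, which are dropped).
#'
#' @param ann An annotation tibble.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "lncorth") {
  ann <- as_annotation(ann)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ann$seq_id, source, ann$start + 1L, ann$end, ann$strand,
    ann$gene_id, ann$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}
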