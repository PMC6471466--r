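test_that("an exon inside a gap-free identical block projects perfectly", {
  b <- block_tbl("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
                 src_start = 100, tgt_start = 500)
  p <- project_exon("chr1", 105, 115, b)
  expect_equal(p$identity, 1)
  expect_equal(p$coverage, 1)
  expect_equal(p$tgt_end - p$tgt_start, 10L)
  expect_equal(p$tgt_start, 505L)
})

test_that("an exon outside all blocks has no projection and zero coverage", {
  b <- block_tbl("ACGT", "ACGT", src_start = 0, tgt_start = 0)
  p <- project_exon("chr1", 1000, 1100, b)
  expect_true(is.na(p$tgt_start))
  expect_equal(p$coverage, 0)
  expect_equal(p$aligned_columns, 0L)
})

test_that("mismatches and target gaps count as aligned non-matches (hand fixture)", {
  # 20 source positions; 3 mismatches, 2 target-gap columns -> 15/20
  src <- "AAAAAAAAAAAAAAAAAAAA"
  tgt <- "AAAAACCCAAAAAAAA--AA"
  b <- block_tbl(src, tgt, src_start = 0, tgt_start = 0)
  p <- project_exon("chr1", 0, 20, b)
  expect_equal(p$aligned_columns, 20L)
  expect_equal(p$matches, 15L)
  expect_equal(p$identity, 0.75)
})

test_that("source-gap columns are skipped and N never matches", {
  # src has 1 gap column (not a source position); one N column
  src <- "AC-GTN"
  tgt <- "ACAGTN"
  b <- block_tbl(src, tgt, src_start = 0, tgt_start = 0)
  p <- project_exon("chr1", 0, 5, b)
  expect_equal(p$aligned_columns, 5L)   # 5 source positions
  expect_equal(p$matches, 4L)           # N-N column does not match
  expect_equal(p$tgt_end - p$tgt_start, 6L)
})

test_that("identity equals a brute-force column count on 100 random gapped blocks", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(30:80, 1)
    src_chars <- sample(c("A", "C", "G", "T"), n, TRUE)
    tgt_chars <- src_chars
    tgt_chars <- mutate_positions(tgt_chars, sample.int(n, sample(0:10, 1)))
    # punch gaps into either row (never both in one column)
    gap_cols <- sample.int(n, sample(0:6, 1))
    side <- sample(c("s", "t"), length(gap_cols), TRUE)
    s <- src_chars; t <- tgt_chars
    s[gap_cols[side == "s"]] <- "-"
    t[gap_cols[side == "t"]] <- "-"
    src_start <- sample(0:1000, 1)
    blk <- block_tbl(paste(s, collapse = ""), paste(t, collapse = ""),
                     src_start = src_start, tgt_start = sample(0:1000, 1))
    src_len <- sum(s != "-")
    lo <- sample.int(src_len, 1) - 1L
    hi <- sample(lo:(src_len - 1), 1) + 1L
    p <- project_exon("chr1", src_start + lo, src_start + hi, blk)
    o <- oracle_project_exon(src_start + lo, src_start + hi, blk)
    expect_equal(p$aligned_columns, o$aligned)
    expect_equal(p$matches, o$matches)
    expect_equal(p$identity, o$identity)
  }
})

test_that("overlapping source blocks are rejected as ambiguous", {
  b1 <- block_tbl("ACGTACGT", "ACGTACGT", src_start = 0, tgt_start = 0)
  b2 <- block_tbl("ACGTACGT", "ACGTACGT", src_start = 4, tgt_start = 100)
  expect_error(project_exons(exon_tbl(0, 8), dplyr::bind_rows(b1, b2)),
               "ambiguous|overlap")
})

test_that("the 60% identity boundary is inclusive and 59% fails", {
  mk_block <- function(n_match, n_total, src_start) {
    s <- rep("A", n_total)
    t <- c(rep("A", n_match), rep("C", n_total - n_match))
    block_tbl(paste(s, collapse = ""), paste(t, collapse = ""),
              src_start = src_start, tgt_start = src_start + 5000)
  }
  ann60 <- exon_tbl(0, 100, tx = "g60.t", gene = "g60")
  pr60 <- project_genes(ann60, mk_block(60, 100, 0))
  expect_equal(pr60$genes$gene_identity, 0.60)
  expect_true(pr60$genes$ortholog_call)
  ann59 <- exon_tbl(0, 100, tx = "g59.t", gene = "g59")
  pr59 <- project_genes(ann59, mk_block(59, 100, 0))
  expect_false(pr59$genes$ortholog_call)
  expect_equal(pr59$genes$reason, "low_identity")
})

test_that("raising the identity threshold never adds ortholog calls", {
  set.seed(73)
  anns <- list(); blks <- list()
  for (i in 1:30) {
    st <- (i - 1) * 1000
    n <- 200
    s <- sample(c("A", "C", "G", "T"), n, TRUE)
    t <- mutate_positions(s, sample.int(n, sample(0:150, 1)))
    anns[[i]] <- exon_tbl(st, st + n, tx = sprintf("g%02d.t", i),
                          gene = sprintf("g%02d", i))
    blk <- block_tbl(paste(s, collapse = ""), paste(t, collapse = ""),
                     src_start = st, tgt_start = 50000 + st)
    blk$block <- i
    blks[[i]] <- blk
  }
  ann <- dplyr::bind_rows(anns); blocks <- dplyr::bind_rows(blks)
  n_calls <- vapply(seq(0.1, 0.9, by = 0.1), function(thr) {
    sum(project_genes(ann, blocks, identity_threshold = thr)$genes$ortholog_call)
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("genes whose exons hit opposite target strands are never called orthologs", {
  b1 <- block_tbl(strrep("A", 30), strrep("A", 30), src_start = 0, tgt_start = 0)
  b2 <- block_tbl(strrep("A", 30), strrep("A", 30), src_start = 100,
                  tgt_start = 400, tgt_strand = "-")
  b2$block <- 2L
  ann <- exon_tbl(c(0, 100), c(30, 130), tx = "g.t", gene = "g")
  pr <- project_genes(ann, dplyr::bind_rows(b1, b2))
  expect_false(pr$genes$ortholog_call)
  expect_equal(pr$genes$reason, "split_projection")
})

test_that("projection through inverted blocks brings exons back home", {
  set.seed(79)
  s <- random_seq(400)
  t_chars <- mutate_positions(strsplit(s, "")[[1]], sample.int(400, 30))
  fwd <- block_tbl(s, paste(t_chars, collapse = ""),
                   src_start = 1000, tgt_start = 9000)
  inv <- block_tbl(paste(t_chars, collapse = ""), s,
                   src_start = 9000, tgt_start = 1000,
                   src_seq = "tchr1", tgt_seq = "chr1")
  p1 <- project_exon("chr1", 1100, 1200, fwd)
  p2 <- project_exons(
    tibble::tibble(seq_id = "tchr1", start = p1$tgt_start, end = p1$tgt_end,
                   strand = "+"),
    inv
  )
  expect_true(p2$tgt_start <= 1100 && p2$tgt_end >= 1200)
})

test_that("target models assemble projected exons, dropping missing ones with a flag", {
  b <- block_tbl(strrep("ACGT", 30), strrep("ACGT", 30),
                 src_start = 0, tgt_start = 2000)
  # exon 2 lies outside the block
  ann <- exon_tbl(c(0, 300, 60), c(40, 400, 110), tx = "tx1", gene = "g1")
  pr <- project_genes(ann, b)
  tm <- build_target_annotation(pr$exons)
  expect_equal(nrow(tm$annotation), 2L)
  expect_equal(tm$transcripts$flag, "partial;short")
  expect_equal(tm$annotation$start, sort(tm$annotation$start))
  # a fully covered 3-exon transcript assembles completely
  ann2 <- exon_tbl(c(0, 40, 80), c(30, 70, 118), tx = "tx2", gene = "g2")
  tm2 <- build_target_annotation(project_genes(ann2, b)$exons)
  expect_equal(nrow(tm2$annotation), 3L)
  expect_equal(tm2$transcripts$flag, "short")
  expect_equal(tm2$summary$n_transcripts, 1L)
})

test_that("the target-model summary equals a recount of its own output", {
  w <- shared_world()
  ann <- read_gtf(w$paths[["sample_1"]])
  lnc <- dplyr::filter(ann, grepl("^LN", gene_id))
  pr <- project_genes(lnc, w$blocks)
  tm <- build_target_annotation(pr$exons)
  kept <- dplyr::filter(tm$transcripts, !flag %in% c("unprojected", "split"))
  expect_equal(tm$summary$n_genes, dplyr::n_distinct(kept$gene_id))
  expect_equal(tm$summary$n_transcripts, nrow(kept))
  recount <- tm$annotation |>
    dplyr::group_by(transcript_id) |>
    dplyr::summarise(bp = sum(end - start))
  expect_equal(tm$summary$max_spliced_bp, max(recount$bp))
  expect_equal(tm$summary$n_ge_min_bp, sum(recount$bp >= 200))
})
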