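test_that("GTF coordinates convert between 1-based inclusive and internal 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), path)
  ann <- read_gtf(path)
  expect_equal(ann$start, c(0L, 200L))
  expect_equal(ann$end, c(100L, 300L))
  expect_equal(ann$end - ann$start, c(100L, 100L))
  expect_equal(dplyr::n_distinct(ann$transcript_id), 1L)
  expect_equal(nrow(ann), 2L)
})

test_that("out-of-order exon lines are sorted and the intron chain is unchanged", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t501\t600\t.\t-\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t1\t100\t.\t-\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t201\t300\t.\t-\t.\tgene_id "g"; transcript_id "t";'
  ), path)
  ann <- read_gtf(path)
  expect_equal(ann$start, c(0L, 200L, 500L))
  tx <- transcript_summary(ann)
  expect_equal(tx$intron_chain, "100:200;300:500")
})

test_that("malformed GTF input errors with the line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1\tx\texon\t1\t100"
  ), path)
  expect_error(read_gtf(path), "line 2")
  writeLines(c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g";'
  ), path)
  expect_error(read_gtf(path), "transcript_id")
})

test_that("GTF round-trips exactly, including 100 random transcripts", {
  path <- withr::local_tempfile(fileext = ".gtf")
  # empty annotation -> empty file -> empty annotation
  empty <- as_annotation(exon_tbl(integer(), integer())[0, ])
  write_gtf(empty, path)
  expect_equal(nrow(read_gtf(path)), 0L)

  set.seed(11)
  anns <- lapply(1:100, function(i) {
    n_ex <- sample(1:5, 1)
    gaps <- sample(10:500, n_ex, replace = TRUE)
    lens <- sample(50:400, n_ex, replace = TRUE)
    starts <- sample(0:10000, 1) + cumsum(gaps + c(0L, lens[-n_ex]))
    ends <- starts + lens
    exon_tbl(starts, ends, tx = sprintf("t%03d", i), gene = sprintf("g%03d", i),
             seq = sample(c("chr1", "chr2"), 1), strand = sample(c("+", "-"), 1))
  })
  ann <- as_annotation(dplyr::bind_rows(anns))
  write_gtf(ann, path)
  back <- read_gtf(path)
  expect_equal(back, ann)
})

test_that("MAF blocks parse with normalised forward-strand coordinates", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "##maf version=1",
    "a score=0",
    "s srcA 10 10 + 1000 ACGTACGTAC",
    "s tgtB 20 10 + 2000 ACGTACGTAC",
    "",
    "a score=0",
    "s srcA 30 10 + 1000 ACGTACGTAC",
    "s tgtB 40  9 + 2000 ACGTAC-TAC"
  ), path)
  b <- read_maf(path)
  expect_equal(nrow(b), 2L)
  expect_equal(b$src_end - b$src_start, c(10L, 10L))
  expect_equal(b$tgt_end - b$tgt_start, c(10L, 9L))
  expect_equal(b$block, 1:2)
})

test_that("minus-strand MAF rows convert to forward coordinates preserving reverse complement", {
  # forward target sequence positions 2000-10-4 = 1986..1995 hold the
  # reverse complement of the aligned text
  path <- withr::local_tempfile(fileext = ".maf")
  txt <- "ACGTTTGGCA"
  writeLines(c(
    "a",
    paste("s src 5 10 + 1000", txt),
    paste("s tgt 4 10 - 2000", txt)
  ), path)
  b <- read_maf(path)
  expect_equal(b$tgt_strand, "-")
  expect_equal(b$tgt_start, 2000L - 4L - 10L)
  expect_equal(b$tgt_end, 2000L - 4L)
  expect_equal(revcomp(b$tgt_text), revcomp(txt))
})

test_that("MAF parsing rejects non-pairwise blocks and inconsistent rows", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "a",
    "s a 0 4 + 100 ACGT",
    "s b 0 4 + 100 ACGT",
    "s c 0 4 + 100 ACGT"
  ), path)
  expect_error(read_maf(path), "pairwise")
  writeLines(c(
    "a",
    "s a 0 4 + 100 ACGT",
    "s b 0 4 + 100 ACG-T"
  ), path)
  expect_error(read_maf(path), "unequal|size")
})

test_that("MAF write/read round-trips including minus-strand rows", {
  set.seed(3)
  b1 <- block_tbl(random_seq(40), random_seq(40), src_start = 100, tgt_start = 700)
  b2 <- block_tbl(random_seq(30), random_seq(30), src_start = 500, tgt_start = 60,
                  tgt_strand = "-")
  b2$block <- 2L
  blocks <- dplyr::bind_rows(b1, b2)
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(blocks, path)
  expect_equal(read_maf(path), blocks)
})

test_that("transcripts with identical intron chains merge with union termini", {
  a <- exon_tbl(c(100, 300), c(200, 400), tx = "tA")
  b <- exon_tbl(c(150, 300), c(200, 450), tx = "tB", gene = "tA")
  merged <- merge_transcripts(list(s1 = a, s2 = b))
  expect_equal(nrow(merged), 2L)
  expect_equal(min(merged$start), 100L)
  expect_equal(max(merged$end), 450L)
  expect_equal(unique(merged$samples), "s1,s2")
  # internal boundary untouched
  expect_true(all(c(200L, 300L) %in% c(merged$start, merged$end)))
})

test_that("merging is idempotent and order-independent", {
  set.seed(5)
  a <- exon_tbl(c(0, 500, 900), c(100, 700, 1000), tx = "t1")
  b <- exon_tbl(c(2000, 2500), c(2100, 2600), tx = "t2", strand = "-")
  s1 <- dplyr::bind_rows(a, b)
  m1 <- merge_transcripts(list(x = s1, y = s1, z = s1))
  expect_equal(nrow(m1), nrow(s1))
  m12 <- merge_transcripts(list(x = s1, y = a))
  m21 <- merge_transcripts(list(y = a, x = s1))
  expect_equal(
    dplyr::arrange(m12, transcript_id, start),
    dplyr::arrange(m21, transcript_id, start)
  )
})

test_that("a 1-bp intron boundary difference keeps transcripts separate", {
  a <- exon_tbl(c(100, 300), c(200, 400), tx = "tA")
  b <- exon_tbl(c(100, 301), c(200, 400), tx = "tB")
  merged <- merge_transcripts(list(s1 = a, s2 = b))
  expect_equal(dplyr::n_distinct(merged$transcript_id), 2L)
})

test_that("single-exon transcripts merge only on exact interval identity", {
  a <- exon_tbl(100, 500, tx = "tA")
  b <- exon_tbl(100, 500, tx = "tB")
  c3 <- exon_tbl(100, 501, tx = "tC")
  merged <- merge_transcripts(list(s1 = a, s2 = b, s3 = c3))
  expect_equal(dplyr::n_distinct(merged$transcript_id), 2L)
})

test_that("annotations tagged as different genomes refuse to merge", {
  a <- exon_tbl(c(0, 200), c(100, 300))
  b <- a
  attr(a, "genome") <- "bosTau8"
  attr(b, "genome") <- "hg19"
  expect_error(merge_transcripts(list(a, b)), "different genomes")
})

test_that("spliced sequences respect strand and exon order", {
  genome <- c(chr1 = "AAACCCGGGTTT")
  ann <- exon_tbl(c(0, 9), c(3, 12), tx = "p", strand = "+")
  expect_equal(unname(spliced_sequences(ann, genome)["p"]), "AAATTT")
  ann_m <- exon_tbl(c(0, 9), c(3, 12), tx = "m", strand = "-")
  expect_equal(unname(spliced_sequences(ann_m, genome)["m"]), "AAATTT")
  ann_m2 <- exon_tbl(c(3, 6), c(6, 9), tx = "m2", strand = "-")
  expect_equal(unname(spliced_sequences(ann_m2, genome)["m2"]), "CCCGGG")
})

test_that("exon-table invariants are enforced", {
  expect_error(as_annotation(exon_tbl(10, 10)), "start < end")
  expect_error(as_annotation(exon_tbl(c(0, 50), c(100, 150))), "disjoint")
  bad <- exon_tbl(c(0, 200), c(100, 300))
  bad$strand <- c("+", "-")
  expect_error(as_annotation(bad), "contract|strand")
})
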