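test_that("structural filter applies the 200-bp and multi-exon rules with inclusive boundary", {
  ann <- dplyr::bind_rows(
    exon_tbl(c(0, 200), c(100, 300), tx = "ok200"),      # spliced 200: kept
    exon_tbl(c(1000, 1300), c(1099, 1400), tx = "len199"), # spliced 199
    exon_tbl(5000, 10000, tx = "mono")                    # 1 exon, 5000 bp
  )
  dec <- filter_structural(ann)
  expect_equal(dec$kept[dec$transcript_id == "ok200"], TRUE)
  expect_equal(dec$reason[dec$transcript_id == "len199"], "too_short")
  expect_equal(dec$reason[dec$transcript_id == "mono"], "single_exon")
  # partition: exactly one row per transcript, one reason iff removed
  expect_equal(sort(dec$transcript_id), sort(unique(ann$transcript_id)))
  expect_true(all(is.na(dec$reason) == dec$kept))
})

test_that("raising the length threshold never grows the kept set", {
  set.seed(21)
  ann <- dplyr::bind_rows(lapply(1:50, function(i) {
    lens <- sample(60:250, 2)
    exon_tbl(c(0, 400), c(lens[1], 400 + lens[2]), tx = sprintf("t%02d", i))
  }))
  kept_sets <- lapply(c(100, 200, 300, 400), function(thr) {
    d <- filter_structural(ann, min_length_bp = thr)
    d$transcript_id[d$kept]
  })
  for (i in 2:length(kept_sets)) {
    expect_true(all(kept_sets[[i]] %in% kept_sets[[i - 1]]))
  }
})

test_that("longest ORF scan matches hand examples and a brute-force oracle", {
  r <- longest_orf("ATGAAATAG")
  expect_equal(r$aa_length, 2L)
  expect_equal(r$frame, 0L)
  expect_equal(r$start, 0L)
  # no ATG -> no ORF
  expect_equal(longest_orf("CCCCCCCCCCCC")$aa_length, 0L)
  # stop required: ATG with no downstream stop is not a complete ORF
  expect_equal(longest_orf("ATGAAAAAAAAA")$aa_length, 0L)

  brute <- function(s) {
    best <- 0L
    n <- nchar(s)
    for (st in 1:max(1, n - 2)) {
      if (substring(s, st, st + 2) != "ATG") next
      pos <- st + 3
      while (pos + 2 <= n) {
        if (substring(s, pos, pos + 2) %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (pos - st) / 3)
          break
        }
        pos <- pos + 3
      }
    }
    as.integer(best)
  }
  set.seed(31)
  for (i in 1:20) {
    s <- random_seq(600)
    expect_equal(longest_orf(s)$aa_length, brute(s))
  }
})

test_that("coding model separates synthetic classes and retrains identically", {
  set.seed(41)
  train <- generate_training_sequences(60)
  test <- generate_training_sequences(40)
  m <- train_coding_model(train$coding, train$noncoding)
  held_out <- c(
    score_coding_potential(m, test$coding) >= 0.5,
    score_coding_potential(m, test$noncoding) < 0.5
  )
  expect_gte(mean(held_out), 0.95)
  m2 <- train_coding_model(train$coding, train$noncoding)
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$hexamer_log_odds, m2$hexamer_log_odds)
})

test_that("identical positive and negative classes give chance-level accuracy", {
  set.seed(43)
  seqs <- vapply(1:25, function(i) random_seq(400), character(1))
  m <- train_coding_model(seqs, seqs)
  expect_lt(abs(m$training_accuracy - 0.5), 0.11)
})

test_that("training refuses classes below 20 sequences", {
  seqs <- vapply(1:25, function(i) random_seq(300), character(1))
  expect_error(train_coding_model(seqs[1:10], seqs), "training data")
})

test_that("the coding score depends only on the spliced sequence", {
  set.seed(47)
  train <- generate_training_sequences(30)
  m <- train_coding_model(train$coding, train$noncoding)
  genome <- c(chrZ = random_seq(2000), chrY = random_seq(2000))
  ann1 <- exon_tbl(c(100, 500), c(300, 700), tx = "a", seq = "chrZ")
  seq1 <- spliced_sequences(ann1, genome)
  expect_identical(
    score_coding_potential(m, unname(seq1)),
    score_coding_potential(m, unname(seq1))
  )
  # same sequence string from a different locus scores identically
  expect_equal(
    unname(score_coding_potential(m, seq1)),
    unname(score_coding_potential(m, setNames(seq1, "other")))
  )
})

test_that("model serialisation round-trips bit-exactly", {
  set.seed(53)
  train <- generate_training_sequences(25)
  m <- train_coding_model(train$coding, train$noncoding)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coding_model(m, path)
  m2 <- read_coding_model(path)
  expect_identical(unname(m$coefficients), unname(m2$coefficients))
  expect_identical(unname(m$hexamer_log_odds), unname(m2$hexamer_log_odds))
  s <- random_seq(500)
  expect_identical(score_coding_potential(m, s), score_coding_potential(m2, s))
})

test_that("coding-potential filter removes sense overlaps and high scorers, keeps antisense", {
  set.seed(59)
  train <- generate_training_sequences(30)
  m <- train_coding_model(train$coding, train$noncoding)
  genome <- c(chr1 = random_seq(6000))
  coding <- exon_tbl(c(1000, 1600), c(1400, 2000), tx = "pc1", gene = "pcg1")
  sense <- exon_tbl(c(1200, 2400), c(1500, 2600), tx = "sense_ov")
  anti <- exon_tbl(c(1200, 2400), c(1500, 2600), tx = "anti_ov", strand = "-")
  away <- exon_tbl(c(4000, 4500), c(4300, 4800), tx = "clear")
  dec <- filter_coding_potential(dplyr::bind_rows(sense, anti, away),
                                 genome, m, coding)
  expect_equal(dec$reason[dec$transcript_id == "sense_ov"], "annotation_overlap")
  expect_true(dec$kept[dec$transcript_id == "anti_ov"])
  expect_true(dec$kept[dec$transcript_id == "clear"])
  # partition with exactly one reason per removed transcript
  expect_true(all(is.na(dec$reason) == dec$kept))
})
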