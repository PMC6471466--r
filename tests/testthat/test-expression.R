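test_that("TPM matches closed forms and handles degenerate samples", {
  m1 <- matrix(c(7, 0), nrow = 1, dimnames = list("f1", c("s1", "s2")))
  tpm1 <- compute_tpm(m1, c(f1 = 500))
  expect_equal(tpm1["f1", "s1"], 1e6)
  expect_equal(tpm1["f1", "s2"], 0)

  m2 <- matrix(c(10, 10), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  tpm2 <- compute_tpm(m2, c(a = 1000, b = 2000))
  expect_equal(unname(tpm2[, 1]), c(2e6 / 3, 1e6 / 3))

  set.seed(101)
  m3 <- matrix(rpois(60, 50), nrow = 10,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  tpm3 <- compute_tpm(m3, setNames(sample(200:3000, 10), paste0("f", 1:10)))
  expect_equal(unname(colSums(tpm3)), rep(1e6, 6), tolerance = 1e-9)
})

test_that("expressed calls use an inclusive mean-count boundary", {
  m <- rbind(at = c(20, 20, 20), below = c(19, 19, 19), mixed = c(0, 60, 30))
  colnames(m) <- paste0("s", 1:3)
  calls <- call_expressed(m, min_mean_reads = 20)
  expect_true(calls$expressed[calls$feature_id == "at"])
  expect_false(calls$expressed[calls$feature_id == "below"])
  expect_true(calls$expressed[calls$feature_id == "mixed"])
})

test_that("BH adjustment equals the hand step-up rule on small vectors", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.007), 0.007)
  set.seed(103)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p))
  }
  # monotone in sorted p, never below raw, re-adjustment never decreases
  p <- runif(10)
  q <- benjamini_hochberg(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(benjamini_hochberg(q) >= q))
  expect_true(all(q >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("constant features are null and groups of one are refused", {
  m <- matrix(50, nrow = 3, ncol = 6,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  fit <- nb_de_test(m, paste0("s", 1:3), paste0("s", 4:6))
  r <- tidy(fit)
  expect_equal(r$log2_fc, rep(0, 3))
  expect_equal(r$p_value, rep(1, 3))
  expect_error(nb_de_test(m, "s1", paste0("s", 2:6)), "at least 2")
})

test_that("swapping the groups negates fold changes and preserves p-values", {
  set.seed(107)
  m <- matrix(rnbinom(200 * 8, mu = 120, size = 20), nrow = 200,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:8)))
  ab <- tidy(nb_de_test(m, paste0("s", 1:4), paste0("s", 5:8)))
  ba <- tidy(nb_de_test(m, paste0("s", 5:8), paste0("s", 1:4)))
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("planted fold changes are recovered with small bias", {
  set.seed(109)
  n <- 200
  n_de <- 40
  mu0 <- exp(rnorm(n, log(200), 0.4))
  eff <- c(rep(c(2, -2), n_de / 2), rep(0, n - n_de))
  ma <- matrix(rnbinom(n * 5, mu = rep(mu0, 5), size = 1 / 0.05), nrow = n)
  mb <- matrix(rnbinom(n * 5, mu = rep(mu0 * 2^eff, 5), size = 1 / 0.05), nrow = n)
  m <- cbind(ma, mb)
  dimnames(m) <- list(paste0("f", 1:n), paste0("s", 1:10))
  r <- tidy(nb_de_test(m, paste0("s", 1:5), paste0("s", 6:10)))
  err <- r$log2_fc[1:n_de] - eff[1:n_de]
  expect_lte(abs(mean(err)), 0.15)
})

test_that("the null p-value distribution is calibrated", {
  set.seed(113)
  n <- 2000
  mu0 <- exp(rnorm(n, log(150), 0.6))
  m <- matrix(rnbinom(n * 10, mu = rep(mu0, 10), size = 1 / 0.05), nrow = n,
              dimnames = list(paste0("f", 1:n), paste0("s", 1:10)))
  r <- tidy(nb_de_test(m, paste0("s", 1:5), paste0("s", 6:10)))
  frac <- mean(r$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("fold-change estimates track an independent NB GLM route", {
  skip_if_not_installed("DESeq2")
  set.seed(127)
  n <- 60
  mu0 <- exp(rnorm(n, log(200), 0.4))
  eff <- c(rep(2, 10), rep(-2, 10), rep(0, n - 20))
  ma <- matrix(rnbinom(n * 4, mu = rep(mu0, 4), size = 20), nrow = n)
  mb <- matrix(rnbinom(n * 4, mu = rep(mu0 * 2^eff, 4), size = 20), nrow = n)
  m <- cbind(ma, mb)
  dimnames(m) <- list(paste0("f", 1:n), paste0("s", 1:8))
  mine <- tidy(nb_de_test(m, paste0("s", 1:4), paste0("s", 5:8)))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = m,
    colData = data.frame(group = factor(rep(c("A", "B"), each = 4),
                                        levels = c("A", "B"))),
    design = ~group
  ))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  expect_gt(cor(mine$log2_fc, ref$log2FoldChange), 0.95)
  expect_gt(cor(-log10(mine$p_value + 1e-300),
                -log10(ref$pvalue + 1e-300)), 0.8)
})

test_that("DEG thresholds are strict and two-sided", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    base_mean = 100,
    log2_fc = c(1.0, 1.5, -2, 3),
    p_value = c(1e-4, 1e-4, 1e-4, 0.5),
    fdr = c(0.005, 0.01, 0.001, 0.6)
  )
  deg <- apply_deg_thresholds(res)
  expect_false(deg$is_deg[deg$feature_id == "a"])  # fold exactly 2
  expect_false(deg$is_deg[deg$feature_id == "b"])  # fdr exactly 0.01
  expect_true(deg$is_deg[deg$feature_id == "c"])   # down-regulation counts
  expect_false(deg$is_deg[deg$feature_id == "d"])
})
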