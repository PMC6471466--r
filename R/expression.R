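#' Transcripts-per-million normalisation
#'
#' `TPM_f = (count_f / length_kb_f) / sum_g(count_g / length_kb_g) * 1e6`
#' per sample.  Columns of the result sum to one million whenever the
#' sample has any count; all-zero samples give all-zero columns rather
#' than `NaN`.
#'
#' @param counts Integer matrix of counts, features in rows, samples in
#'   columns (rownames = feature ids), or a data frame whose first column
#'   is the feature id.
#' @param lengths Numeric vector of feature lengths in bp, in row order or
#'   named by feature.
#' @return A numeric matrix of TPM values with the same dimnames.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as_count_matrix(counts)
  if (!is.null(names(lengths))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0), all(counts >= 0))
  rate <- counts / (lengths / 1e3)
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  tpm
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    ids <- counts[[1]]
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    return(m)
  }
  counts
}

#' Call features expressed by mean raw count
#'
#' A feature is expressed in a sample set when its mean raw count over the
#' selected samples reaches `min_mean_reads` (the boundary value passes).
#'
#' @param counts Count matrix or data frame (see [compute_tpm()]).
#' @param samples Character vector of sample (column) names to average
#'   over; default all columns.
#' @param min_mean_reads Expression threshold on the mean (default 20).
#' @return A tibble with `feature_id`, `mean_count`, `expressed`.
#' @export
call_expressed <- function(counts, samples = NULL, min_mean_reads = 20) {
  counts <- as_count_matrix(counts)
  samples <- samples %||% colnames(counts)
  if (length(samples) < 1) abort("at least one sample must be selected")
  m <- rowMeans(counts[, samples, drop = FALSE])
  tibble::tibble(
    feature_id = rownames(counts),
    mean_count = unname(m),
    expressed = unname(m) >= min_mean_reads
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation:
#' adjusted values are monotone in the sorted p-values, at least the raw
#' value, and at most 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Negative-binomial differential expression test
#'
#' A transparent two-group test in the mould of count-based RNA-seq
#' analysis: median-of-ratios size factors; per-feature method-of-moments
#' negative-binomial dispersion (variance `mu + alpha * mu^2`, pooled
#' within-group, floored at 1e-8) moderated by shrinkage towards the
#' central dispersion of the data set (weights `n_a + n_b - 2` on the
#' feature and `prior_df` on the centre — with few replicates the raw
#' per-feature dispersion is far too noisy to test against, the same
#' reason DESeq2 and limma share dispersion information across genes); a
#' Wald statistic on the log2 fold change of normalised group means
#' (pseudocount 0.5) referred to a t distribution with
#' `n_a + n_b - 2 + prior_df` degrees of freedom; two-sided p-values and
#' BH adjustment.
#' Swapping the groups negates the fold change and preserves p-values.
#'
#' @param counts Count matrix or data frame (see [compute_tpm()]).
#' @param group_a,group_b Character vectors of sample names; the fold
#'   change is condition B over A.  Each group needs at least 2 samples.
#' @param prior_df Weight (in pseudo-degrees of freedom) of the central
#'   dispersion in the shrinkage (default 20).
#' @return An object of class `nb_de` with a `results` tibble
#'   (`feature_id`, `base_mean`, `log2_fc`, `p_value`, `fdr`), the size
#'   factors and the group definition.  Use [tidy()] to extract the
#'   results, [apply_deg_thresholds()] to add DEG calls, [autoplot()] for
#'   a volcano plot.
#' @export
nb_de_test <- function(counts, group_a, group_b, prior_df = 20) {
  counts <- as_count_matrix(counts)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing) > 0) {
    abort(paste0("sample(s) not in count matrix: ", paste(missing, collapse = ", ")))
  }
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  na <- length(group_a)
  nb <- length(group_b)
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  mu_a <- rowMeans(a)
  mu_b <- rowMeans(b)
  base_mean <- rowMeans(norm)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  disp_raw <- pmax((pooled_var - base_mean) / base_mean^2, 1e-8)
  disp_raw[!is.finite(disp_raw)] <- 1e-8
  d <- na + nb - 2
  central <- disp_raw[base_mean >= 5]
  disp_central <- if (length(central) > 0) median(central) else median(disp_raw)
  disp <- (prior_df * disp_central + d * disp_raw) / (prior_df + d)
  log2_fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  se2 <- function(mu, n) {
    m <- mu + 0.5
    (m + disp * m^2) / (n * m^2 * log(2)^2)
  }
  se <- sqrt(se2(mu_a, na) + se2(mu_b, nb))
  tstat <- ifelse(se > 0, log2_fc / se, 0)
  df <- na + nb - 2 + prior_df
  p <- 2 * pt(-abs(tstat), df = df)
  p <- pmin(p, 1)
  results <- tibble::tibble(
    feature_id = rownames(sub) %||% as.character(seq_len(nrow(sub))),
    base_mean = unname(base_mean),
    log2_fc = unname(log2_fc),
    dispersion = unname(disp),
    stat = unname(tstat),
    p_value = unname(p),
    fdr = benjamini_hochberg(unname(p))
  )
  structure(
    list(results = results, size_factors = sf,
         group_a = group_a, group_b = group_b, df = df),
    class = "nb_de"
  )
}

size_factors <- function(counts) {
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  }
  sf <- apply(counts, 2, function(col) {
    exp(median(log(col[usable]) - loggeo[usable]))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' @export
print.nb_de <- function(x, ...) {
  cat("<nb_de> ", nrow(x$results), " features; B (", length(x$group_b),
      " samples) vs A (", length(x$group_a), " samples)\n", sep = "")
  print(x$results)
  invisible(x)
}

#' Tidiers for `nb_de` objects
#'
#' @param x An `nb_de` object.
#' @param ... Unused.
#' @return `tidy()`: the per-feature results tibble.  `glance()`: a
#'   one-row tibble with feature and sample counts and the number of
#'   features at `fdr < 0.05`.
#' @method tidy nb_de
#' @export
tidy.nb_de <- function(x, ...) x$results

#' @rdname tidy.nb_de
#' @method glance nb_de
#' @export
glance.nb_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$results),
    n_samples = length(x$group_a) + length(x$group_b),
    df = x$df,
    n_fdr_05 = sum(x$results$fdr < 0.05)
  )
}

#' Apply fold-change and FDR thresholds to DE results
#'
#' A feature is a DEG when its linear fold change strictly exceeds
#' `fc_threshold` in either direction (`|log2_fc| > log2(fc_threshold)`)
#' and its adjusted p-value is strictly below `fdr_threshold`.
#'
#' @param x An `nb_de` object or its `results` tibble.
#' @param fc_threshold Linear fold-change threshold, strict (default 2).
#' @param fdr_threshold FDR threshold, strict (default 0.01).
#' @return The results tibble with an added logical `is_deg` column.
#' @export
apply_deg_thresholds <- function(x, fc_threshold = 2, fdr_threshold = 0.01) {
  results <- if (inherits(x, "nb_de")) x$results else x
  dplyr::mutate(
    results,
    is_deg = abs(.data$log2_fc) > log2(fc_threshold) & .data$fdr < fdr_threshold
  )
}
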