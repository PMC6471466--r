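#' Train a logistic coding-potential model
#'
#' A lightweight, transparent coding-potential classifier over four
#' classical sequence features: longest-ORF length (log scale), ORF
#' coverage of the transcript, mean hexamer log-odds (coding vs noncoding
#' hexamer frequencies learned from the training sets), and GC fraction.
#' The score is the fitted logistic probability that a sequence is
#' protein-coding, in `[0, 1]`.  Training is fully deterministic.
#'
#' @param coding_seqs Character vector of protein-coding training
#'   sequences (at least 20).
#' @param noncoding_seqs Character vector of noncoding training sequences
#'   (at least 20).
#' @return An object of class `coding_potential_model` with elements
#'   `coefficients`, `hexamer_log_odds`, `training_accuracy`, `n_coding`,
#'   `n_noncoding`.
#' @seealso [score_coding_potential()], [write_coding_model()], [tidy()],
#'   [glance()].
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs) {
  if (length(coding_seqs) < 20 || length(noncoding_seqs) < 20) {
    abort("each training class needs at least 20 sequences; provide more training data")
  }
  coding_seqs <- toupper(coding_seqs)
  noncoding_seqs <- toupper(noncoding_seqs)
  hex <- hexamer_log_odds_table(coding_seqs, noncoding_seqs)
  feats <- rbind(
    sequence_features(coding_seqs, hex),
    sequence_features(noncoding_seqs, hex)
  )
  y <- c(rep(1L, length(coding_seqs)), rep(0L, length(noncoding_seqs)))
  # ridge-penalised logistic fit: training classes are often perfectly
  # separable, where the unpenalised MLE diverges and stops generalising
  fit <- ridge_logistic(feats, y, lambda = 1)
  scores <- plogis(cbind(1, feats) %*% fit$raw_coefficients)[, 1]
  acc <- mean((scores >= 0.5) == (y == 1))
  structure(
    list(
      coefficients = fit$raw_coefficients,
      hexamer_log_odds = hex,
      training_accuracy = acc,
      n_coding = length(coding_seqs),
      n_noncoding = length(noncoding_seqs)
    ),
    class = "coding_potential_model"
  )
}

# IRLS for logistic regression with an L2 penalty (lambda * I) on the
# standardised slopes, intercept unpenalised; returns coefficients mapped
# back to the raw feature scale
ridge_logistic <- function(feats, y, lambda = 1, max_iter = 50, tol = 1e-10) {
  mu <- colMeans(feats)
  sd_ <- apply(feats, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- cbind(1, sweep(sweep(feats, 2, mu), 2, sd_, "/"))
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    prob <- plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-10)
    z <- eta + (y - prob) / w
    new_beta <- solve(crossprod(Z, Z * w) + pen, crossprod(Z, w * z))[, 1]
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  slopes <- beta[-1] / sd_
  raw <- c(beta[1] - sum(slopes * mu), slopes)
  names(raw) <- c("(Intercept)", colnames(feats))
  list(raw_coefficients = raw, standardized = beta)
}

#' Score sequences with a coding-potential model
#'
#' @param model A `coding_potential_model` from [train_coding_model()] or
#'   [read_coding_model()].
#' @param seq Character vector of sequences.
#' @return Numeric vector of coding probabilities in `[0, 1]`.  The score
#'   depends only on the sequence, never on ids or coordinates.
#' @export
score_coding_potential <- function(model, seq) {
  stopifnot(inherits(model, "coding_potential_model"))
  feats <- sequence_features(toupper(seq), model$hexamer_log_odds)
  plogis(cbind(1, feats) %*% model$coefficients)[, 1]
}

sequence_features <- function(seqs, hex) {
  orf <- longest_orf(seqs)
  len <- nchar(seqs)
  orf_nt <- ifelse(is.na(orf$start), 0L, orf$end - orf$start)
  t(vapply(seq_along(seqs), function(i) {
    c(
      log_orf_aa = log10(orf$aa_length[i] + 1),
      orf_coverage = orf_nt[i] / max(len[i], 1L),
      hexamer_score = hexamer_score_one(seqs[i], hex),
      gc = gc_fraction(seqs[i])
    )
  }, numeric(4)))
}

gc_fraction <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(0.5)
  mean(chars[acgt] %in% c("G", "C"))
}

all_hexamers <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      b4 = bases, b5 = bases, b6 = bases,
                      stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

hexamer_counts <- function(seqs) {
  counts <- setNames(numeric(4096), all_hexamers())
  for (s in seqs) {
    n <- nchar(s)
    if (n < 6) next
    hx <- substring(s, 1:(n - 5), 6:n)
    hx <- hx[!grepl("[^ACGT]", hx)]
    if (length(hx) == 0) next
    tab <- table(hx)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts
}

hexamer_log_odds_table <- function(coding_seqs, noncoding_seqs) {
  cc <- hexamer_counts(coding_seqs)
  nc <- hexamer_counts(noncoding_seqs)
  # +1 pseudocount keeps unseen hexamers finite
  log((cc + 1) / sum(cc + 1)) - log((nc + 1) / sum(nc + 1))
}

hexamer_score_one <- function(s, hex) {
  n <- nchar(s)
  if (n < 6) return(0)
  hx <- substring(s, 1:(n - 5), 6:n)
  hx <- hx[!grepl("[^ACGT]", hx)]
  if (length(hx) == 0) return(0)
  mean(hex[hx])
}

#' @export
print.coding_potential_model <- function(x, ...) {
  cat("<coding_potential_model>\n")
  cat("  trained on", x$n_coding, "coding /", x$n_noncoding, "noncoding sequences\n")
  cat("  training accuracy:", sprintf("%.3f", x$training_accuracy), "\n")
  cat("  coefficients:", paste(sprintf("%s=%.3g", names(x$coefficients), x$coefficients),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a coding-potential model
#'
#' @param x A `coding_potential_model`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of model terms and weights. `glance()`: a
#'   one-row tibble with training-set size and accuracy.
#' @method tidy coding_potential_model
#' @export
tidy.coding_potential_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.coding_potential_model
#' @method glance coding_potential_model
#' @export
glance.coding_potential_model <- function(x, ...) {
  tibble::tibble(
    n_coding = x$n_coding,
    n_noncoding = x$n_noncoding,
    training_accuracy = x$training_accuracy
  )
}

#' Serialise a coding-potential model as flat text
#'
#' The model is written as a flat key-value table (weights plus the 4096
#' hexamer log-odds) with full double precision, so
#' `read_coding_model(write_coding_model(m))` reproduces `m` bit-exactly.
#'
#' @param model A `coding_potential_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_coding_model()` returns the model.
#' @export
write_coding_model <- function(model, path) {
  lines <- c(
    sprintf("meta\tn_coding\t%d", model$n_coding),
    sprintf("meta\tn_noncoding\t%d", model$n_noncoding),
    sprintf("meta\ttraining_accuracy\t%s", format_exact(model$training_accuracy)),
    sprintf("coef\t%s\t%s", names(model$coefficients), format_exact(model$coefficients)),
    sprintf("hexamer\t%s\t%s", names(model$hexamer_log_odds), format_exact(model$hexamer_log_odds))
  )
  writeLines(lines, path)
  invisible(path)
}

format_exact <- function(x) sprintf("%.17g", x)

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  df <- readr::read_tsv(path, col_names = c("kind", "key", "value"),
                        col_types = "ccc", progress = FALSE)
  coefs <- df[df$kind == "coef", ]
  hex <- df[df$kind == "hexamer", ]
  meta <- df[df$kind == "meta", ]
  mv <- setNames(meta$value, meta$key)
  structure(
    list(
      coefficients = setNames(as.numeric(coefs$value), coefs$key),
      hexamer_log_odds = setNames(as.numeric(hex$value), hex$key),
      training_accuracy = as.numeric(mv[["training_accuracy"]]),
      n_coding = as.integer(mv[["n_coding"]]),
      n_noncoding = as.integer(mv[["n_noncoding"]])
    ),
    class = "coding_potential_model"
  )
}
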