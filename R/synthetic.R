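#' Specification of the synthetic two-genome world
#'
#' Defines the study conditions emulated by [generate_world()]: a source
#' genome carrying protein-coding genes and several classes of lncRNA
#' loci, a target genome reachable through colinear pairwise alignment
#' blocks with planted per-locus identity, and a gene-level RNA-seq count
#' design over the four conditions native RPE, 4-week culture, 8-week
#' culture and retina.
#'
#' Locus classes and their planted signals:
#' * `coding` — long biased-codon ORFs, conserved with substitutions at
#'   third codon positions (identity `coding_identity`).
#' * `lnc_neutral` — conserved lncRNAs, substitutions uniform over the
#'   locus at `conserved_identity`; a leading subset is planted
#'   expression-responsive (rules `de_both` / `stable_responsive`) and a
#'   subset of those overlaps a target-only coding gene.
#' * `lnc_decoy` — coding-derived decoys: noncoding-looking sequence whose
#'   exonic substitutions are concentrated at third codon positions (the
#'   signal the conservation screen must catch).
#' * `lnc_low` — conserved below the ortholog identity threshold
#'   (`low_identity`).
#' * `lnc_specific` — present only in the source genome (no alignment).
#' * `lnc_single`, `lnc_short` — structural-filter fodder (single exon /
#'   spliced length < 200 bp).
#'
#' @param seed Integer seed; the world is a deterministic function of the
#'   spec.
#' @param n_coding,n_neutral,n_decoy,n_low,n_specific,n_single,n_short
#'   Locus counts per class.
#' @param conserved_identity,coding_identity,low_identity Planted
#'   alignment identities.
#' @param n_rule1,n_rule2 Neutral loci planted DE-responsive under the two
#'   selection rules.
#' @param n_overlap Responsive neutral loci whose target projection is
#'   made to overlap a target-only coding gene (first from rule 1, then
#'   rule 2).
#' @param n_decoy_responsive,n_specific_responsive Decoy / species-
#'   specific loci planted with the rule-1 expression pattern (they must
#'   be eliminated by the sequence screens, not by expression).
#' @param replicates Samples per condition.
#' @param dispersion Negative-binomial dispersion `alpha`
#'   (variance `mu + alpha mu^2`).
#' @param log2fc Magnitude of planted fold changes.
#' @param background_block_fraction Fraction of inter-locus gaps also
#'   covered by an alignment block.
#' @param n_samples Number of per-sample assemblies emitted.
#' @param n_train Training sequences per class for the coding-potential
#'   model.
#' @return A list of class `world_spec`.
#' @export
world_spec <- function(seed = 42,
                       n_coding = 30, n_neutral = 90, n_decoy = 10,
                       n_low = 15, n_specific = 20,
                       n_single = 5, n_short = 3,
                       conserved_identity = 0.85, coding_identity = 0.90,
                       low_identity = 0.40,
                       n_rule1 = 8, n_rule2 = 4, n_overlap = 5,
                       n_decoy_responsive = 2, n_specific_responsive = 2,
                       replicates = 4, dispersion = 0.05, log2fc = 2,
                       background_block_fraction = 0.2,
                       n_samples = 3, n_train = 60) {
  stopifnot(
    conserved_identity >= 0, conserved_identity <= 1,
    low_identity >= 0, low_identity <= 1,
    replicates >= 2, n_rule1 + n_rule2 <= n_neutral,
    n_overlap <= n_rule1 + n_rule2,
    n_decoy_responsive <= n_decoy, n_specific_responsive <= n_specific
  )
  structure(as.list(environment()), class = "world_spec")
}

#' @export
print.world_spec <- function(x, ...) {
  cat("<world_spec> seed", x$seed, "\n")
  cat("  loci:", x$n_coding, "coding,", x$n_neutral, "neutral lnc,",
      x$n_decoy, "decoy,", x$n_low, "low-identity,",
      x$n_specific, "species-specific\n")
  cat("  identities:", x$conserved_identity, "(conserved)",
      x$low_identity, "(low)\n")
  cat("  expression:", x$replicates, "replicates x 4 conditions, alpha =",
      x$dispersion, "\n")
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0))
  setdiff(all, STOP_CODONS)
}

# GC3-skewed codon usage gives training sequences a composition signal
biased_codons <- function(n) {
  codons <- sense_codons()
  w <- ifelse(substr(codons, 3, 3) %in% c("G", "C"), 3, 1)
  sample(codons, n, replace = TRUE, prob = w)
}

coding_sequence <- function(n_codons) {
  paste0("ATG", paste(biased_codons(n_codons - 2L), collapse = ""),
         sample(STOP_CODONS, 1))
}

# resample preserving approximate dinucleotide structure (first-order
# Markov chain fitted to the input)
dinucleotide_shuffle <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) return(s)
  trans <- table(factor(chars[-n], levels = c("A", "C", "G", "T")),
                 factor(chars[-1], levels = c("A", "C", "G", "T")))
  trans <- trans + 0.5
  out <- character(n)
  out[1] <- chars[1]
  bases <- c("A", "C", "G", "T")
  for (i in 2:n) {
    p <- trans[out[i - 1], ]
    out[i] <- sample(bases, 1, prob = p)
  }
  paste(out, collapse = "")
}

#' Generate labelled training sequences for the coding-potential model
#'
#' Coding class: transcripts with a biased-codon ORF of at least 100
#' codons flanked by short UTRs.  Noncoding class: first-order
#' dinucleotide shuffles of the coding sequences, which preserve
#' composition but destroy the reading frame.
#'
#' @param n_per_class Sequences per class (at least 20).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A list with character vectors `coding` and `noncoding`.
#' @export
generate_training_sequences <- function(n_per_class = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_per_class >= 20)
  coding <- vapply(seq_len(n_per_class), function(i) {
    orf <- coding_sequence(sample(100:200, 1))
    paste0(random_dna(sample(20:60, 1)), orf, random_dna(sample(20:60, 1)))
  }, character(1))
  noncoding <- vapply(coding, dinucleotide_shuffle, character(1),
                      USE.NAMES = FALSE)
  list(coding = coding, noncoding = noncoding)
}

# kill chance open reading frames by mutating their start codons until
# no complete ORF longer than max_aa remains
disrupt_orfs <- function(spliced, max_aa = 50L) {
  repeat {
    orf <- longest_orf(spliced)
    if (orf$aa_length <= max_aa) return(spliced)
    substr(spliced, orf$start + 3L, orf$start + 3L) <- sample(c("A", "C", "T"), 1)
  }
}

# genome positions of a transcript's spliced sequence, 5' to 3'
spliced_positions <- function(exons, strand) {
  pos <- unlist(purrr::map2(exons$start, exons$end, function(s, e) seq.int(s, e - 1L)))
  if (strand == "-") rev(pos) else pos
}

#' Generate the synthetic two-genome world
#'
#' Deterministically (given the spec) builds and writes: the source and
#' target genome FASTAs, the source and target protein-coding reference
#' GTFs, per-sample transcript-assembly GTFs with jittered transcript
#' termini, a pairwise MAF whose blocks carry the planted per-locus
#' identities, a gene-level count matrix over the four-condition design,
#' a truth table of every planted label, and training FASTAs for the
#' coding-potential model.
#'
#' @param spec A [world_spec()].
#' @param dir Output directory (created if needed).
#' @return A list of class `lnc_world` with `paths` (named file paths),
#'   `truth` (planted-truth tibble), `condition_map` (named vector sample
#'   to condition), `spec`, and the in-memory `blocks`, `src_genome`,
#'   `tgt_genome`.
#' @export
generate_world <- function(spec, dir) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  loci <- plan_loci(spec)
  src_len <- max(loci$exons_df$end) + 2000L
  if (src_len > 5e7) abort("infeasible spec: loci exceed supported genome length")
  src <- strsplit(random_dna(src_len), "", fixed = TRUE)[[1]]

  # write coding ORFs into coding-gene exons; make lncRNA loci clearly
  # noncoding by disrupting chance ORFs in (and 60 bp around) their exons
  for (i in seq_len(nrow(loci$table))) {
    ex <- loci$exons_df[loci$exons_df$gene_id == loci$table$gene_id[i], ]
    strand <- loci$table$strand[i]
    if (loci$table$class[i] == "coding") {
      L <- sum(ex$end - ex$start)
      src <- write_spliced(src, ex, strand, coding_sequence(L / 3L))
    } else {
      ext <- ex
      ext$start[which.min(ext$start)] <- ext$start[which.min(ext$start)] - 60L
      ext$end[which.max(ext$end)] <- ext$end[which.max(ext$end)] + 60L
      pos <- spliced_positions(ext, strand)
      spliced <- paste(src[pos + 1L], collapse = "")
      if (strand == "-") spliced <- chartr("ACGT", "TGCA", spliced)
      spliced <- disrupt_orfs(spliced, max_aa = 50L)
      src <- write_spliced(src, ext, strand, spliced)
    }
  }
  src_genome <- c(src_chr1 = paste(src, collapse = ""))

  world <- build_alignment(spec, loci, src)
  blocks <- world$blocks
  tgt_genome <- c(tgt_chr1 = world$tgt_seq)

  expr <- plan_expression(spec, loci$table)
  counts <- simulate_counts(spec, expr)

  truth <- dplyr::left_join(loci$table, expr$truth, by = "gene_id") |>
    dplyr::left_join(world$locus_identity, by = "gene_id")

  paths <- write_world_files(spec, dir, loci, src_genome, tgt_genome,
                             blocks, world, counts, expr, truth)

  structure(
    list(paths = paths, truth = truth, condition_map = expr$condition_map,
         spec = spec, blocks = blocks, src_genome = src_genome,
         tgt_genome = tgt_genome),
    class = "lnc_world"
  )
}

#' @export
print.lnc_world <- function(x, ...) {
  cat("<lnc_world> seed", x$spec$seed, "-", nrow(x$truth), "loci,",
      nrow(x$blocks), "alignment blocks\n")
  cat("  files under:", dirname(x$paths[["src_genome"]]), "\n")
  invisible(x)
}

# ---- internal world builders ------------------------------------------

plan_loci <- function(spec) {
  classes <- c(
    rep("coding", spec$n_coding), rep("lnc_neutral", spec$n_neutral),
    rep("lnc_decoy", spec$n_decoy), rep("lnc_low", spec$n_low),
    rep("lnc_specific", spec$n_specific), rep("lnc_single", spec$n_single),
    rep("lnc_short", spec$n_short)
  )
  prefix <- c(coding = "CG", lnc_neutral = "LN", lnc_decoy = "LD",
              lnc_low = "LL", lnc_specific = "LS", lnc_single = "LX",
              lnc_short = "LT")
  ids <- unlist(lapply(split(seq_along(classes), classes), function(ix) {
    sprintf("%s%03d", prefix[[classes[ix[1]]]], seq_along(ix))
  })[unique(classes)])
  order_ix <- sample(seq_along(classes))
  cursor <- 2000L
  rows <- list()
  exon_rows <- list()
  gaps <- list()
  prev_end <- 0L
  for (k in order_ix) {
    cls <- classes[k]
    gid <- ids[k]
    gap <- sample(800:2000, 1)
    gaps[[length(gaps) + 1L]] <- c(prev_end + 100L, cursor + gap - 100L)
    cursor <- cursor + gap
    strand <- sample(c("+", "-"), 1)
    if (cls == "coding") {
      n_ex <- 3L
      ex_len <- 3L * sample(50:100, n_ex, replace = TRUE)
    } else if (cls == "lnc_single") {
      n_ex <- 1L
      ex_len <- sample(400:600, 1)
    } else if (cls == "lnc_short") {
      n_ex <- 2L
      ex_len <- c(40L, 40L)
    } else {
      n_ex <- sample(2:4, 1)
      ex_len <- sample(140:400, n_ex, replace = TRUE)
    }
    introns <- if (n_ex > 1) sample(150:500, n_ex - 1, replace = TRUE) else integer(0)
    starts <- cursor + c(0L, cumsum(ex_len[-n_ex] + introns))
    ends <- starts + ex_len
    exon_rows[[k]] <- tibble::tibble(
      seq_id = "src_chr1", start = starts, end = ends, strand = strand,
      transcript_id = paste0(gid, ".t1"), gene_id = gid
    )
    rows[[k]] <- tibble::tibble(
      gene_id = gid, class = cls, strand = strand,
      span_start = starts[1], span_end = ends[n_ex],
      spliced_bp = sum(ex_len), n_exons = n_ex
    )
    cursor <- ends[n_ex]
    prev_end <- ends[n_ex]
  }
  list(
    table = dplyr::bind_rows(rows[order_ix]),
    exons_df = dplyr::bind_rows(exon_rows[order_ix]),
    gaps = gaps
  )
}

write_spliced <- function(src_chars, exons, strand, spliced) {
  pos <- spliced_positions(exons, strand)
  chars <- strsplit(spliced, "", fixed = TRUE)[[1]]
  if (strand == "-") {
    chars <- chartr("ACGTN", "TGCAN", chars)  # pos already 3'->5' reversed
  }
  src_chars[pos + 1L] <- chars
  src_chars
}

build_alignment <- function(spec, loci, src_chars) {
  tab <- loci$table
  aligned <- tab[tab$class %in% c("coding", "lnc_neutral", "lnc_decoy", "lnc_low"), ]
  aligned <- aligned[order(aligned$span_start), ]
  tgt_pieces <- list()
  block_rows <- list()
  id_rows <- list()
  tcursor <- 1000L
  tgt_gap_seqs <- list(random_dna(1000L))
  for (i in seq_len(nrow(aligned))) {
    g <- aligned[i, ]
    identity <- switch(g$class,
      coding = spec$coding_identity,
      lnc_neutral = spec$conserved_identity,
      lnc_decoy = spec$conserved_identity,
      lnc_low = spec$low_identity
    )
    rs <- g$span_start - 100L
    re <- g$span_end + 100L
    region <- src_chars[(rs + 1L):re]
    len <- length(region)
    n_sub <- round((1 - identity) * len)
    ex <- loci$exons_df[loci$exons_df$gene_id == g$gene_id, ]
    sub_pos <- pick_substitution_positions(g$class, ex, g$strand, rs, len, n_sub)
    tgt_region <- substitute_bases(region, sub_pos)
    block_rows[[i]] <- tibble::tibble(
      block = i,
      src_seq = "src_chr1", src_start = rs, src_end = re,
      src_strand = "+", src_size = NA_integer_,
      tgt_seq = "tgt_chr1", tgt_start = tcursor, tgt_end = tcursor + len,
      tgt_strand = "+", tgt_size = NA_integer_,
      src_text = paste(region, collapse = ""),
      tgt_text = paste(tgt_region, collapse = "")
    )
    id_rows[[i]] <- tibble::tibble(
      gene_id = g$gene_id,
      planted_identity = identity,
      tgt_region_start = tcursor,
      src_region_start = rs
    )
    tgt_pieces[[i]] <- paste(tgt_region, collapse = "")
    gap <- sample(500:1500, 1)
    tgt_gap_seqs[[i + 1L]] <- random_dna(gap)
    tcursor <- tcursor + len + gap
  }
  # background blocks over a fraction of inter-locus gaps
  n_bg <- round(spec$background_block_fraction * length(loci$gaps))
  usable_gaps <- Filter(function(gp) gp[2] - gp[1] > 900, loci$gaps)
  n_bg <- min(n_bg, length(usable_gaps))
  bg_rows <- list()
  if (n_bg > 0) {
    pick <- sample(seq_along(usable_gaps), n_bg)
    for (j in seq_len(n_bg)) {
      gp <- usable_gaps[[pick[j]]]
      blen <- sample(300:800, 1)
      bs <- gp[1] + sample.int(gp[2] - gp[1] - blen, 1)
      region <- src_chars[(bs + 1L):(bs + blen)]
      tgt_region <- substitute_bases(region, sample.int(blen, round(0.15 * blen)))
      bg_rows[[j]] <- tibble::tibble(
        block = nrow(aligned) + j,
        src_seq = "src_chr1", src_start = bs, src_end = bs + blen,
        src_strand = "+", src_size = NA_integer_,
        tgt_seq = "tgt_chr1", tgt_start = tcursor, tgt_end = tcursor + blen,
        tgt_strand = "+", tgt_size = NA_integer_,
        src_text = paste(region, collapse = ""),
        tgt_text = paste(tgt_region, collapse = "")
      )
      tgt_pieces[[length(tgt_pieces) + 1L]] <- paste(tgt_region, collapse = "")
      gap <- sample(500:1500, 1)
      tgt_gap_seqs[[length(tgt_gap_seqs) + 1L]] <- random_dna(gap)
      tcursor <- tcursor + blen + gap
    }
  }
  tgt_seq <- paste(
    unlist(purrr::map2(tgt_gap_seqs, c(tgt_pieces, list("")), c)),
    collapse = ""
  )
  blocks <- dplyr::bind_rows(c(block_rows, bg_rows))
  blocks$src_size <- length(src_chars)
  blocks$tgt_size <- nchar(tgt_seq)
  list(
    blocks = blocks, tgt_seq = tgt_seq,
    locus_identity = dplyr::bind_rows(id_rows)
  )
}

# decoy and coding loci concentrate exonic substitutions on third codon
# positions of the spliced frame; neutral/low loci substitute uniformly
pick_substitution_positions <- function(class, exons, strand, region_start, len, n_sub) {
  if (n_sub == 0) return(integer(0))
  if (class %in% c("lnc_neutral", "lnc_low")) {
    return(sample.int(len, min(n_sub, len)))
  }
  sp <- spliced_positions(exons, strand)          # genome coords, 5'->3'
  third <- sp[seq_along(sp) %% 3 == 0]            # spliced index 3, 6, ...
  third_in_region <- third - region_start + 1L    # 1-based offsets in region
  exonic_quota <- round((n_sub / len) * length(sp))
  exonic_quota <- min(exonic_quota, length(third_in_region), n_sub)
  exonic <- sample(third_in_region, exonic_quota)
  exonic_all <- sp - region_start + 1L
  nonexonic_pool <- setdiff(seq_len(len), exonic_all)
  n_rest <- min(n_sub - exonic_quota, length(nonexonic_pool))
  c(exonic, sample(nonexonic_pool, n_rest))
}

substitute_bases <- function(chars, pos) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  chars
}

plan_expression <- function(spec, tab) {
  lnc_neutral <- tab$gene_id[tab$class == "lnc_neutral"]
  rule1 <- head(lnc_neutral, spec$n_rule1)
  rule2 <- head(setdiff(lnc_neutral, rule1), spec$n_rule2)
  responsive <- c(rule1, rule2)
  overlap <- head(c(rule1, rule2), spec$n_overlap)
  decoy_resp <- head(tab$gene_id[tab$class == "lnc_decoy"], spec$n_decoy_responsive)
  specific_resp <- head(tab$gene_id[tab$class == "lnc_specific"], spec$n_specific_responsive)

  n <- nrow(tab)
  is_resp <- tab$gene_id %in% c(responsive, decoy_resp, specific_resp)
  base <- ifelse(
    is_resp,
    rlnorm(n, log(300), 0.3),
    ifelse(runif(n) < 0.2, rlnorm(n, log(5), 0.5), rlnorm(n, log(150), 0.6))
  )
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  lfc_retina <- numeric(n)
  lfc_cult <- numeric(n)
  r1 <- tab$gene_id %in% c(rule1, decoy_resp, specific_resp)
  r2 <- tab$gene_id %in% rule2
  lfc_retina[r1] <- sgn(sum(r1)) * spec$log2fc
  lfc_cult[r1] <- sgn(sum(r1)) * spec$log2fc
  lfc_cult[r2] <- sgn(sum(r2)) * spec$log2fc

  conditions <- c("native", "cult4w", "cult8w", "retina")
  samples <- unlist(lapply(conditions, function(cd) {
    paste0(cd, "_", seq_len(spec$replicates))
  }))
  condition_map <- setNames(rep(conditions, each = spec$replicates), samples)

  truth <- tibble::tibble(
    gene_id = tab$gene_id,
    base_mean_planted = base,
    lfc_retina = lfc_retina,
    lfc_cult4 = lfc_cult,
    lfc_cult8 = lfc_cult,
    responsive_rule = dplyr::case_when(
      tab$gene_id %in% rule1 ~ "de_both",
      tab$gene_id %in% rule2 ~ "stable_responsive",
      tab$gene_id %in% decoy_resp ~ "decoy_de_both",
      tab$gene_id %in% specific_resp ~ "specific_de_both",
      TRUE ~ NA_character_
    ),
    overlaps_target_coding = tab$gene_id %in% overlap,
    conserved_true = tab$class == "lnc_neutral" &
      tab$gene_id %in% responsive & !tab$gene_id %in% overlap
  )
  list(truth = truth, condition_map = condition_map,
       overlap_genes = overlap)
}

simulate_counts <- function(spec, expr) {
  truth <- expr$truth
  cmap <- expr$condition_map
  mu_for <- function(cond) {
    lfc <- switch(cond,
      native = 0, retina = truth$lfc_retina,
      cult4w = truth$lfc_cult4, cult8w = truth$lfc_cult8
    )
    truth$base_mean_planted * 2^lfc
  }
  m <- sapply(names(cmap), function(s) {
    mu <- mu_for(cmap[[s]])
    rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
  })
  rownames(m) <- truth$gene_id
  m
}

write_world_files <- function(spec, dir, loci, src_genome, tgt_genome,
                              blocks, world, counts, expr, truth) {
  p <- function(f) file.path(dir, f)
  write_genome(src_genome, p("src_genome.fa"))
  write_genome(tgt_genome, p("tgt_genome.fa"))

  coding_ann <- loci$exons_df[loci$exons_df$gene_id %in%
                                loci$table$gene_id[loci$table$class == "coding"], ]
  write_gtf(coding_ann, p("src_coding.gtf"))

  # target coding annotation: coding genes lifted through their (gap-free)
  # blocks, plus target-only genes planted over designated candidates
  li <- world$locus_identity
  tgt_coding <- dplyr::inner_join(coding_ann, li, by = "gene_id") |>
    dplyr::transmute(
      seq_id = "tgt_chr1",
      start = .data$tgt_region_start + (.data$start - .data$src_region_start),
      end = .data$tgt_region_start + (.data$end - .data$src_region_start),
      strand = .data$strand,
      transcript_id = paste0(.data$transcript_id, "_h"),
      gene_id = paste0(.data$gene_id, "_h")
    )
  first_exons <- loci$exons_df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(ex1 = min(.data$start), .groups = "drop")
  ovl <- dplyr::inner_join(
    tibble::tibble(gene_id = expr$overlap_genes), li, by = "gene_id"
  ) |>
    dplyr::inner_join(first_exons, by = "gene_id") |>
    dplyr::transmute(
      seq_id = "tgt_chr1",
      start = .data$tgt_region_start + (.data$ex1 - .data$src_region_start) - 50L,
      end = .data$tgt_region_start + (.data$ex1 - .data$src_region_start) + 150L,
      strand = "+",
      transcript_id = paste0("OVL_", .data$gene_id, ".t1"),
      gene_id = paste0("OVL_", .data$gene_id)
    )
  write_gtf(dplyr::bind_rows(tgt_coding, ovl), p("tgt_coding.gtf"))

  sample_paths <- character(spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    ann <- loci$exons_df
    if (s > 1) {
      keep_gene <- unique(ann$gene_id)[runif(dplyr::n_distinct(ann$gene_id)) > 0.15]
      ann <- ann[ann$gene_id %in% keep_gene, ]
    }
    ann <- jitter_termini(ann)
    sample_paths[s] <- p(sprintf("sample_%d.gtf", s))
    write_gtf(ann, sample_paths[s])
  }

  write_maf(blocks, p("alignment.maf"))

  counts_df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(counts_df, p("counts.tsv"))
  readr::write_tsv(truth, p("truth.tsv"))

  train <- generate_training_sequences(spec$n_train)
  write_genome(setNames(train$coding, paste0("coding_", seq_along(train$coding))),
               p("train_coding.fa"))
  write_genome(setNames(train$noncoding, paste0("noncoding_", seq_along(train$noncoding))),
               p("train_noncoding.fa"))

  c(
    src_genome = p("src_genome.fa"), tgt_genome = p("tgt_genome.fa"),
    src_coding = p("src_coding.gtf"), tgt_coding = p("tgt_coding.gtf"),
    maf = p("alignment.maf"), counts = p("counts.tsv"),
    truth = p("truth.tsv"),
    train_coding = p("train_coding.fa"), train_noncoding = p("train_noncoding.fa"),
    setNames(sample_paths, paste0("sample_", seq_len(spec$n_samples)))
  )
}

# per-sample wobble of transcript termini; intron chains are untouched so
# merging collapses the copies
jitter_termini <- function(ann) {
  ann |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      start = ifelse(dplyr::row_number() == 1,
                     .data$start - sample(0:50, 1), .data$start),
      end = ifelse(dplyr::row_number() == dplyr::n(),
                   .data$end + sample(0:50, 1), .data$end)
    ) |>
    dplyr::ungroup()
}

#' Plant a genomic-context classification fixture
#'
#' Builds, deterministically up to small jitters, a coding annotation and
#' a candidate set with exact planted class counts: `n_genic` candidates
#' fully inside a coding gene span, `n_spanning` candidates straddling a
#' gene boundary, and `n_intergenic` candidates overlapping nothing.
#' Useful for verifying that the context classifier's three-way partition
#' is exhaustive and recovers planted truth.
#'
#' @param n_genic,n_intergenic,n_spanning Planted class counts.
#' @param n_genes Number of coding genes to spread candidates over.
#' @param seed Seed for strand/offset jitter.
#' @return A list with `candidates` and `coding` annotation tibbles and
#'   `truth` (tibble of `transcript_id`, `class`).
#' @export
simulate_context_candidates <- function(n_genic = 157, n_intergenic = 542,
                                        n_spanning = 149, n_genes = 100,
                                        seed = 1) {
  set.seed(seed)
  spacing <- 40000L
  gene_span <- 5000L
  gstart <- (seq_len(n_genes) - 1L) * spacing + 10000L
  coding <- tibble::tibble(
    seq_id = "chrA",
    start = rep(gstart, each = 2) + rep(c(0L, 3500L), n_genes),
    end = rep(gstart, each = 2) + rep(c(1500L, gene_span), n_genes),
    strand = rep(sample(c("+", "-"), n_genes, replace = TRUE), each = 2),
    transcript_id = rep(sprintf("pc%03d.t1", seq_len(n_genes)), each = 2),
    gene_id = rep(sprintf("pc%03d", seq_len(n_genes)), each = 2)
  )
  genic <- candidate_rows(n_genic, "genic", gstart, n_genes,
                          function(gs, k) gs + 500L + (k %% 10L) * 100L, 1000L)
  spanning <- candidate_rows(n_spanning, "span", gstart, n_genes,
                             function(gs, k) gs + gene_span - 500L - (k %% 5L) * 50L, 2000L)
  intergenic <- candidate_rows(n_intergenic, "inter", gstart, n_genes,
                               function(gs, k) gs + gene_span + 3000L + (k %% 20L) * 800L, 900L)
  candidates <- dplyr::bind_rows(genic, spanning, intergenic)
  truth <- tibble::tibble(
    transcript_id = c(unique(genic$transcript_id),
                      unique(spanning$transcript_id),
                      unique(intergenic$transcript_id)),
    class = rep(c("genic", "spanning", "intergenic"),
                c(n_genic, n_spanning, n_intergenic))
  )
  list(candidates = as_annotation(candidates), coding = as_annotation(coding),
       truth = truth)
}

candidate_rows <- function(n, prefix, gstart, n_genes, offset_fun, len) {
  if (n == 0) return(empty_annotation())
  g <- ((seq_len(n) - 1L) %% n_genes) + 1L
  span_start <- offset_fun(gstart[g], seq_len(n))
  # two exons so candidates pass structural filters too
  ex_start <- as.integer(c(span_start, span_start + len - 300L))
  ex_end <- as.integer(c(span_start + 300L, span_start + len))
  tibble::tibble(
    seq_id = "chrA",
    start = ex_start,
    end = ex_end,
    strand = rep(sample(c("+", "-"), n, replace = TRUE), 2),
    transcript_id = rep(sprintf("%s%04d", prefix, seq_len(n)), 2),
    gene_id = rep(sprintf("%s%04d", prefix, seq_len(n)), 2)
  )
}
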