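#' Pipeline configuration
#'
#' Gathers every input path and numeric threshold of the end-to-end
#' analysis in one flat, serialisable object.  Thresholds default to the
#' values the analysis is defined with: candidates must be multi-exon and
#' at least 200 bp spliced; ortholog calls need at least 60% alignment
#' identity (boundary inclusive) and 50% exon coverage; DEGs need fold
#' change strictly above 2 and FDR strictly below 0.01; expression calls
#' need a mean of at least 20 raw reads; the coding-conservation screen
#' runs at alpha 0.01.
#'
#' @param src_genome,tgt_genome FASTA paths of the two genomes.
#' @param sample_gtfs Character vector of per-sample assembly GTFs.
#' @param src_coding,tgt_coding Protein-coding reference GTFs.
#' @param maf Pairwise alignment MAF path.
#' @param counts Count matrix TSV (first column `gene_id`, then samples).
#' @param condition_map Named character vector mapping sample names to
#'   conditions `native`, `cult4w`, `cult8w`, `retina`.
#' @param train_coding,train_noncoding Training FASTAs for the
#'   coding-potential model.
#' @param min_length_bp,min_exons Structural filter thresholds.
#' @param coding_score_threshold Coding-potential score cut-off.
#' @param identity_threshold,coverage_threshold Ortholog-call thresholds.
#' @param fc_threshold,fdr_threshold DEG thresholds (strict).
#' @param min_mean_reads Expressed-call threshold (inclusive).
#' @param coding_alpha Conservation-screen significance level.
#' @param window_bp Context-subtype window.
#' @param studied_denominator Optional denominator override for the
#'   conservation fraction; defaults to the number of candidate lncRNA
#'   genes entering projection.
#' @param outdir Optional directory for report TSV/GTF output.
#' @return A list of class `pipeline_config`.
#' @seealso [run_pipeline()], [write_config()], [read_config()]
#' @export
pipeline_config <- function(src_genome, tgt_genome, sample_gtfs,
                            src_coding, tgt_coding, maf, counts,
                            condition_map, train_coding, train_noncoding,
                            min_length_bp = 200, min_exons = 2,
                            coding_score_threshold = 0.5,
                            identity_threshold = 0.60,
                            coverage_threshold = 0.5,
                            fc_threshold = 2, fdr_threshold = 0.01,
                            min_mean_reads = 20, coding_alpha = 0.01,
                            window_bp = 10000,
                            studied_denominator = NULL, outdir = NULL) {
  cfg <- as.list(environment())[names(formals(pipeline_config))]
  stopifnot(
    min_length_bp >= 1, min_exons >= 1,
    coding_score_threshold >= 0, coding_score_threshold <= 1,
    identity_threshold >= 0, identity_threshold <= 1,
    coverage_threshold >= 0, coverage_threshold <= 1,
    fc_threshold > 0, fdr_threshold > 0, fdr_threshold <= 1,
    min_mean_reads >= 0, coding_alpha > 0, coding_alpha < 1
  )
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration from a generated world
#'
#' @param world An `lnc_world` from [generate_world()].
#' @param ... Threshold overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
world_config <- function(world, ...) {
  p <- world$paths
  pipeline_config(
    src_genome = p[["src_genome"]], tgt_genome = p[["tgt_genome"]],
    sample_gtfs = unname(p[grepl("^sample_", names(p))]),
    src_coding = p[["src_coding"]], tgt_coding = p[["tgt_coding"]],
    maf = p[["maf"]], counts = p[["counts"]],
    condition_map = world$condition_map,
    train_coding = p[["train_coding"]], train_noncoding = p[["train_noncoding"]],
    ...
  )
}

#' Serialise / load a pipeline configuration
#'
#' Flat YAML with one key per configuration field;
#' `read_config(write_config(cfg))` returns an equal object.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config()`: `path` invisibly. `read_config()`: the
#'   configuration.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$condition_map <- as.list(x$condition_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$condition_map <- unlist(x$condition_map)
  x$sample_gtfs <- unlist(x$sample_gtfs)
  do.call(pipeline_config, x)
}

#' Run the full conserved-lncRNA pipeline
#'
#' Executes the chain: merge per-sample assemblies by intron chain;
#' structural and coding-potential candidate filters; genomic-context
#' classification; exon projection through the pairwise alignment with
#' ortholog calling; codon-position coding-conservation purge;
#' negative-binomial differential expression for retina vs native and
#' each culture time point vs native; expressed calls; candidate
#' selection by the two evidence rules; target-coding overlap purge; and
#' the final conservation fraction.  Everything is deterministic given
#' the inputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run`: per-stage tibbles
#'   (`merged`, `structural`, `coding_filter`, `candidates`, `context`,
#'   `projection`, `target_models`, `conservation_screen`, `de` (list per
#'   contrast), `expressed` (list), `selection`, `purge`), the final
#'   `conserved` gene ids, `conservation_percent`, and a stage `manifest`
#'   with input/output counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  note_stage <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out
    )
  }

  samples <- purrr::map(config$sample_gtfs, read_gtf)
  merged <- merge_transcripts(samples)
  n_tx_in <- sum(purrr::map_int(samples, ~ dplyr::n_distinct(.x$transcript_id)))
  note_stage("merge", n_tx_in, dplyr::n_distinct(merged$transcript_id))

  structural <- filter_structural(merged, config$min_length_bp, config$min_exons)
  after_structural <- filter_annotation(merged, structural)
  note_stage("structural_filter", nrow(structural), sum(structural$kept))

  src_genome <- read_genome(config$src_genome)
  src_coding <- read_gtf(config$src_coding)
  train <- list(
    coding = unname(read_genome(config$train_coding)),
    noncoding = unname(read_genome(config$train_noncoding))
  )
  model <- train_coding_model(train$coding, train$noncoding)
  coding_filter <- filter_coding_potential(
    after_structural, src_genome, model, src_coding,
    score_threshold = config$coding_score_threshold
  )
  candidates <- filter_annotation(after_structural, coding_filter)
  note_stage("coding_filter", nrow(coding_filter), sum(coding_filter$kept))

  context <- classify_all(candidates, src_coding, config$window_bp)
  note_stage("context", dplyr::n_distinct(candidates$transcript_id),
             nrow(context$calls))

  blocks <- read_maf(config$maf)
  projection <- project_genes(candidates, blocks,
                              identity_threshold = config$identity_threshold,
                              coverage_threshold = config$coverage_threshold)
  orthologs <- projection$genes$gene_id[projection$genes$ortholog_call]
  note_stage("projection", nrow(projection$genes), length(orthologs))

  ortholog_ann <- dplyr::filter(candidates, .data$gene_id %in% orthologs)
  purge <- purge_coding_like(ortholog_ann, blocks, alpha = config$coding_alpha)
  surviving_genes <- setdiff(orthologs, unique(purge$removed$gene_id))
  note_stage("coding_conservation", length(orthologs), length(surviving_genes))

  target_models <- build_target_annotation(
    dplyr::filter(projection$exons, .data$gene_id %in% surviving_genes),
    min_transcript_bp = config$min_length_bp
  )

  counts <- readr::read_tsv(config$counts, show_col_types = FALSE, progress = FALSE)
  cmap <- config$condition_map
  cond_samples <- function(cond) names(cmap)[cmap == cond]
  de <- list(
    retina = nb_de_test(counts, cond_samples("native"), cond_samples("retina")),
    cult4 = nb_de_test(counts, cond_samples("native"), cond_samples("cult4w")),
    cult8 = nb_de_test(counts, cond_samples("native"), cond_samples("cult8w"))
  )
  deg <- purrr::map(de, function(fit) {
    r <- apply_deg_thresholds(fit, config$fc_threshold, config$fdr_threshold)
    r$feature_id[r$is_deg]
  })
  expressed <- list(
    native = call_expressed(counts, cond_samples("native"), config$min_mean_reads),
    retina = call_expressed(counts, cond_samples("retina"), config$min_mean_reads)
  )
  expressed_ids <- purrr::map(expressed, ~ .x$feature_id[.x$expressed])
  note_stage("expression", nrow(counts), sum(purrr::map_int(deg, length)))

  # selection acts on the lncRNA loci that survived the sequence screens
  selection <- select_candidates(
    de_retina_vs_rpe = deg$retina, de_cult4 = deg$cult4, de_cult8 = deg$cult8,
    expressed_native = expressed_ids$native,
    expressed_retina = expressed_ids$retina,
    universe = surviving_genes
  )
  note_stage("selection", length(surviving_genes), nrow(selection))

  purge_overlap <- purge_target_coding_overlap(
    selection$gene_id, target_models$annotation, read_gtf(config$tgt_coding)
  )
  conserved <- purge_overlap$gene_id[purge_overlap$status == "true_lncRNA"]
  note_stage("target_overlap_purge", nrow(selection), length(conserved))

  lnc_genes <- unique(candidates$gene_id)
  denominator <- config$studied_denominator %||% length(lnc_genes)
  pct <- conservation_fraction(length(conserved), denominator)

  run <- structure(
    list(
      merged = merged, structural = structural, coding_filter = coding_filter,
      candidates = candidates, context = context, model = model,
      projection = projection, coding_conservation = purge,
      target_models = target_models, de = de, deg = deg,
      expressed = expressed, selection = selection,
      purge_overlap = purge_overlap, conserved = conserved,
      studied_denominator = denominator, conservation_percent = pct,
      manifest = dplyr::bind_rows(manifest), config = config
    ),
    class = "pipeline_run"
  )
  if (!is.null(config$outdir)) write_run_reports(run, config$outdir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest)
  cat("conserved true lncRNAs:", length(x$conserved), "of",
      x$studied_denominator, sprintf("(%.2f%%)", x$conservation_percent), "\n")
  invisible(x)
}

write_run_reports <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_gtf(run$candidates, p("candidates.gtf"))
  readr::write_tsv(run$context$calls, p("context.tsv"))
  readr::write_tsv(run$projection$genes, p("projection.tsv"))
  if (nrow(run$target_models$annotation) > 0) {
    write_gtf(run$target_models$annotation, p("projected_models.gtf"))
  }
  if (nrow(run$coding_conservation$screen) > 0) {
    readr::write_tsv(run$coding_conservation$screen, p("coding_conservation.tsv"))
  }
  for (ct in names(run$de)) {
    out <- apply_deg_thresholds(run$de[[ct]], run$config$fc_threshold,
                                run$config$fdr_threshold) |>
      dplyr::select("feature_id", `Base Mean` = "base_mean",
                    `Fold Change` = "log2_fc", pvalue = "p_value",
                    padj = "fdr", "is_deg")
    readr::write_tsv(out, p(paste0("de_", ct, ".tsv")))
  }
  readr::write_tsv(run$purge_overlap, p("conservation_report.tsv"))
  readr::write_tsv(run$manifest, p("manifest.tsv"))
  invisible(outdir)
}

#' Integer-percent rounding used in run summaries
#'
#' @param numerator,denominator Counts.
#' @return `round(100 * numerator / denominator)` as an integer.
#' @examples
#' summary_percent(572, 848)  # 67
#' @export
summary_percent <- function(numerator, denominator) {
  as.integer(round(100 * numerator / denominator))
}

#' Summarise a pipeline run
#'
#' Condenses a [run_pipeline()] result into the headline numbers: context
#' class tallies, the expressed fraction of candidates (integer percent),
#' per-contrast DEG counts with the unique/common decomposition of the
#' two culture time points, candidate and true-lncRNA counts, and the
#' conservation percentage.
#'
#' @param run A `pipeline_run`.
#' @return A list with `context_tally`, `n_candidates`,
#'   `expressed_percent`, `de_counts`, `culture_unique_common`,
#'   `n_selected`, `n_true_lncRNA`, `conservation_percent`.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  lnc_genes <- unique(run$candidates$gene_id)
  expressed_lnc <- intersect(
    run$expressed$native$feature_id[run$expressed$native$expressed], lnc_genes
  )
  c4 <- intersect(run$deg$cult4, lnc_genes)
  c8 <- intersect(run$deg$cult8, lnc_genes)
  list(
    context_tally = run$context$tally,
    n_candidates = length(lnc_genes),
    expressed_percent = summary_percent(length(expressed_lnc), length(lnc_genes)),
    de_counts = purrr::map_int(run$deg, ~ length(intersect(.x, lnc_genes))),
    culture_unique_common = c(
      unique_4wk = length(setdiff(c4, c8)),
      unique_8wk = length(setdiff(c8, c4)),
      common = length(intersect(c4, c8))
    ),
    n_selected = nrow(run$selection),
    n_true_lncRNA = length(run$conserved),
    conservation_percent = run$conservation_percent
  )
}
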