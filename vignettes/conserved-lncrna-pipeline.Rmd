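---
title: "Models and methods: projecting a tissue lncRNA repertoire across genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: projecting a tissue lncRNA repertoire across genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncorth)
```

This vignette is the package's own account of the science it implements:
the models behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic world does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The pipeline and its assumptions

The package reconstructs the conserved, differentially expressed core of a
tissue's lncRNA repertoire in seven stages: assembly merging, structural
and coding-potential filtering, genomic-context classification, ortholog
projection through pairwise whole-genome alignment, a coding-conservation
screen, negative-binomial differential expression, and an evidence-based
selection with a final protein-overlap purge. Three assumptions run
through everything:

1. **Coordinates.** All internal coordinates are 0-based half-open;
   conversion to GTF's 1-based inclusive convention and MAF's
   strand-relative starts happens only in the readers and writers. This
   keeps interval arithmetic (`length = end - start`, adjacency,
   overlap) free of ±1 corrections everywhere else.
2. **Transcript identity.** Two assemblies describe the same transcript
   iff they share sequence, strand and intron chain. Terminal-exon ends
   are coverage artefacts and take the union span on merging; internal
   boundaries are splice sites and are never moved. Single-exon
   transcripts have no intron chain and merge only on exact identity —
   and are then discarded by the structural filter anyway, since
   single-exon assemblies are unreliable.
3. **Stranded transcripts.** Spliced sequences are 5'→3'; ORF scanning
   uses forward frames only, and orientation (sense/antisense,
   divergent/convergent) is always defined relative to an annotated
   coding gene.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_length_bp` | 200 | bp spliced | the conventional lower bound in the lncRNA definition; measured on exonic length, not genomic span, and inclusive (a 200 bp transcript passes) |
| `min_exons` | 2 | exons | single-exon models are assembly noise at typical coverage |
| `coding_score_threshold` | 0.5 | probability | the logistic model's natural midpoint; exposed because upstream tools run with tool-default cutoffs |
| `identity_threshold` | 0.60 | fraction | the "substantial homology" bound for calling an orthologous gene region; inclusive at the boundary |
| `coverage_threshold` | 0.5 | fraction of exonic bp | an ortholog call from a sliver of aligned sequence is meaningless; half the exonic bases must lie in alignment blocks |
| `fc_threshold`, `fdr_threshold` | 2, 0.01 | linear fold, FDR | DEG definition; both strict inequalities, two-sided in fold change |
| `min_mean_reads` | 20 | mean raw reads | expressed-locus call; inclusive |
| `coding_alpha` | 0.01 | significance | the coding-conservation purge, applied to the Bonferroni-corrected p |
| `window_bp` | 10000 | bp | divergent/convergent subtyping window for intergenic loci, the convention of lncRNA classifiers |

## Ortholog projection: the identity accounting, bit-exactly

Identity is counted per *source-aligned column*: a column where the source
row has a gap is not a source position and is skipped entirely; a column
where the target row has a gap is an aligned non-match; `N` never matches;
case is ignored. Gene identity is the match-weighted mean over exon
projections (total matches / total aligned columns), and coverage is the
fraction of exonic bp falling inside any block. This accounting changes
results at the margin — e.g. an exon over 20 aligned columns with 3
mismatches and 2 target gaps has identity 15/20 — so it is fixed in the
documentation and tested against brute-force column counting.

Two safety rules: blocks that overlap on the source genome are an input
error (projection would be ambiguous; the package refuses rather than
silently picking one), and a gene whose exons project to more than one
target sequence or strand is never called an ortholog
(`split_projection`), because no single target gene model exists.

Whether the homology threshold applies per exon, per gene or per
alignment hit was an open choice; the package thresholds the gene-level
weighted mean (single decision per locus, robust to one noisy exon) and
reports per-exon identities so users can re-threshold.

## The coding-conservation screen

Purifying selection on an open reading frame leaves a fingerprint in
cross-species alignments: substitutions crowd into third codon positions,
where most changes are synonymous. The screen assigns each ungapped
column of the spliced pairwise alignment a codon position under each of
the three forward frames, counts substitution columns, and computes a
one-sided exact binomial tail for excess at position 3, with null success
probability equal to the realised fraction of counted columns at position
3 (≈ 1/3, exactly accounting for alignment length mod 3). The best frame
is taken and corrected by a Bonferroni factor of 3. Gap and `N` columns
leave both numerator and denominator, which also makes the statistic
symmetric in the two species. Alignments under 90 ungapped columns
(30 codons) are reported untestable rather than tested underpowered.

The binomial models substitution positions as independent; a permutation
of observed substitution labels is hypergeometric instead, and at high
substitution fractions the two tails can differ by a few percent. The
tests therefore validate the tail against Monte-Carlo simulation of the
binomial null itself. The flag's realised type-I error on neutral
alignments is far below the nominal 0.01 (the exact test is conservative
and Bonferroni stacks on top), which is the right direction for a purge:
false flags remove genuinely conserved lncRNAs.

No dN/dS or codon-model likelihood is attempted; the screen is a
detection statistic for a purge step, not an evolutionary-rate estimate.

## Differential expression: a moderated NB Wald test

The DE stage is deliberately a small, transparent stand-in for a full
count-model package: median-of-ratios size factors; per-feature
method-of-moments NB dispersion (variance $\mu + \alpha\mu^2$) pooled
within groups and floored at $10^{-8}$; a Wald statistic on the log2 fold
change of normalised group means with pseudocount 0.5.

Two numerical choices required care. At 4–5 replicates the raw
method-of-moments $\hat\alpha$ is extremely noisy: plugging it into the
Wald variance either miscalibrates the null (normal reference) or
destroys power (small-df t reference). The resolution is the standard
one — share information across features. $\hat\alpha_i$ is shrunk toward
the data set's central dispersion with prior weight `prior_df = 20`
pseudo-degrees of freedom against the feature's own
$d = n_A + n_B - 2$, and the statistic is referred to a t distribution
with $d + \textit{prior\_df}$ df. Simulation at the package's design
sizes (2000 null NB features, dispersion 0.05, 4 vs 4) puts the fraction
of null p-values below 0.05 at 0.04–0.05, and a cross-check against an
independent NB GLM route (DESeq2, in Suggests) gives fold-change
correlations above 0.95. No shrinkage of fold changes, no outlier
filtering and no independent filtering are attempted — the selection
logic downstream, not the test machinery, is the point.

Fold change is thresholded on the linear scale, two-sided
(`|log2FC| > 1` for the default threshold 2), both DEG inequalities
strict. Expressed is a mean of raw counts (inclusive at 20), kept
separate from DE normalisation on purpose: it mirrors a read-count
screen, not a model fit.

## The coding-potential model

Four classical features — log10 longest-ORF length, ORF coverage, mean
hexamer log-odds and GC fraction — feed a logistic score. The fit is a
ridge-penalised IRLS ($\lambda = 1$ on standardised slopes, intercept
free): labelled training classes are often perfectly separable, where the
unpenalised MLE diverges and its decision boundary, glued to the training
clouds, stops generalising to sequences from neither cloud. The penalty
keeps weights finite and the boundary in feature space sensible; training
remains deterministic, so retraining reproduces weights bit-exactly, and
the model serialises to flat text (5 coefficients + 4096 hexamer
log-odds) with full precision.

The score is a stand-in for external lncRNA classifiers whose exact
feature sets and cutoffs are not reproducible from published defaults; it
is documented, swappable, and its threshold is a config parameter.

## Context classification

The three-way partition — genic, intergenic, spanning — is computed on
*gene spans* (min start to max end over a gene's transcripts), not exon
structure: containment in at least one span is genic, zero overlap is
intergenic, anything else spans. Exon-level sense overlap has already
removed coding contaminants upstream, so span-based classification here
answers a positional question, not an identity question. A candidate
overlapping two genes and intergenic space is simply `spanning` (single
label, no multi-class). Nearest-gene ties break by distance then
lexicographic gene id, making output deterministic; reflection of all
coordinates and strands leaves every class and subtype invariant, which
the tests assert.

## What the synthetic world emulates — and what it does not

`world_spec()` defaults define the study conditions: one source
chromosome carrying 30 coding genes, 90 neutral conserved lncRNAs at 85%
planted identity, 10 coding-derived decoys (same identity, substitutions
concentrated on third codon positions of the spliced frame), 15
low-identity loci at 40%, 20 species-specific loci with no alignment,
plus single-exon and sub-200-bp filter fodder; three per-sample
assemblies with 0–50 bp terminus wobble and 15% per-sample locus dropout;
gap-free alignment blocks covering each conserved locus ±100 bp and a
fifth of the gaps; and a four-condition count design (native, 4- and
8-week culture, retina; 4 replicates; NB dispersion $\alpha = 0.05$;
planted $|log2FC| = 2$). Twelve neutral loci are planted
expression-responsive — eight DE in both retina and culture, four stable
in retina but culture-responsive — and five of them overlap a planted
target-only coding gene, leaving seven true conserved lncRNAs. Identities
sit 25 points above and 20 points below the 60% threshold and effects
4-fold beyond the fold threshold, so planted truth is recoverable exactly
rather than probabilistically. Planted lncRNA sequences are made clearly
noncoding by disrupting chance ORFs over 50 aa (mutating their start
codons) in and 60 bp around the exons — without this, occasional random
loci carry long chance ORFs and are correctly, but unhelpfully for a
planted-truth fixture, removed as coding-like.

Deliberate non-realism, so results on the world do not overstate what
passing tests show about real data: no indels inside alignment blocks
(colinear, gap-free by construction; gapped behaviour is tested on hand
fixtures instead), no repeats, rearrangements or lineage-specific
duplications, uniform substitution placement within a class, no
GC/mappability biases in counts, no batch effects, and counts at gene
level only. Real whole-genome alignments also miss or truncate loci for
reasons other than divergence; the coverage threshold is the package's
explicit stand-in for that failure mode.

Problem sizes throughout (a ~0.5 Mb source genome, 173 loci, 16
samples; 1000-replicate calibration loops; 2000-feature null panels) were
chosen as the smallest at which every planted contrast is decisively
separated from its threshold; the full suite and the acceptance script
each run in a few minutes on one CPU.

## Degenerate inputs and tie-breaks

* Empty annotation or candidate sets flow through every stage as empty
  tibbles, never errors; an empty coding annotation classifies everything
  intergenic/isolated.
* All-zero count columns give all-zero TPM, not `NaN`; size factors fall
  back to 1 when no feature is strictly positive everywhere.
* ORF ties break 5'-most start, then lowest frame; nearest-gene ties by
  distance then gene id; merged transcripts take the lexicographically
  smallest contributing ids, with a `.v` suffix when distinct single-exon
  variants share a source id.
* The identity boundary is inclusive (0.60 calls, 0.59 does not); DEG
  thresholds are strict; the expressed threshold is inclusive. Boundary
  cases are pinned by tests.

## Known limitations

* The intron-chain merge cannot reconcile genuinely conflicting chains
  from different samples; both are kept as separate transcripts of the
  locus.
* Identity is primary-sequence only; lncRNAs conserved in structure but
  not sequence are invisible to the projection, and the screen cannot
  rescue them.
* The DE stand-in has no fold-change shrinkage, so very-low-count fold
  changes are noisy (mitigated, not removed, by the pseudocount).
* "Expressed at the same level" in the selection algebra is
  operationalised as expressed in both tissues and *not* a DEG between
  them; no equivalence band is estimated.
* The studied-set denominator of the conservation fraction is exposed as
  a parameter (`studied_denominator`) rather than fixed, because the
  natural denominator — candidates entering projection, projectable
  candidates, or projectable transcripts over 200 bp — is a reporting
  choice, not a modelling one.
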