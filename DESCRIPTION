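Package: lncorth
Title: Cross-Species Projection and Conservation Screening of Tissue lncRNA Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a tissue long non-coding RNA (lncRNA) repertoire from
    per-sample transcript assemblies, classifies candidate loci by genomic
    context relative to protein-coding annotation, projects their exons
    through pairwise whole-genome alignment blocks into a second genome,
    screens projected loci for cryptic protein-coding conservation using a
    codon-position substitution test, performs negative-binomial differential
    expression with Benjamini-Hochberg FDR control, and intersects expression
    evidence across conditions to isolate the small conserved, differentially
    expressed lncRNA set. Ships a seeded two-genome simulator with planted
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
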