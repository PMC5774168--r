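Package: famexpand
Title: Gene-Family Census and Completeness Metrics for De Novo
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates minimum gene-family sizes (for example cytochrome
    P450s and cathepsins) from a fragmented de novo transcriptome
    assembly.  Transcripts are assigned to reference orthologs by
    exhaustive six-frame translated local alignment, near-identical
    isoforms are collapsed, open-reading-frame completeness is called,
    and truncated transcripts aligning to non-overlapping regions of the
    same reference protein are merged as fragments of one gene.  Also
    provides assembly-completeness diagnostics (N50, contig length
    distributions, ortholog hit ratios, multi-reference hit partitions),
    read- and contig-level quality filters, and a seeded synthetic
    transcriptome generator with a ground-truth ledger for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
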