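Package: regvar
Title: Annotation and Prioritization of Noncoding Somatic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates tumor somatic variants (SNVs and small indels) against a
    bundle of regulatory-genomics resources and ranks them with an
    entropy-weighted scoring scheme trained on natural polymorphisms.
    Includes nucleotide-level motif loss and gain detection with exact
    position-weight-matrix tail p-values computed by dynamic programming,
    linkage of regulatory elements to likely target genes by correlating
    histone-mark, DNA-methylation and expression signals across tissues,
    gene-network centrality scoring, cross-sample recurrence detection, and a
    synthetic data-context generator so the whole pipeline is testable at toy
    scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
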