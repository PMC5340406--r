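Package: rohfunnel
Title: Autozygosity Mapping and Recessive Variant Filtering for Mendelian Disease Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for autozygosity-guided discovery of recessive disease
    variants in inbred populations, modelled on canine SNP-array plus
    whole-genome-sequencing study designs. Implements QC filtering of
    array genotypes, sliding-window detection of runs of homozygosity
    (ROH), intersection of case ROH into shared allele-matched regions, a
    case-specific recessive variant-filtering funnel against a control
    panel, transcript-aware coding-consequence annotation with simplified
    HGVS c./p. notation and truncation statistics, pedigree segregation
    checking, carrier-frequency estimation and allelic 2x2 association
    testing with extreme-tail p-values. A synthetic-cohort simulator with
    a planted causal nonsense variant makes the whole pipeline testable
    end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
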