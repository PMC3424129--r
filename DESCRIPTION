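Package: estssr
Title: EST-SSR Mining, Genic Annotation and Marker Design
Version: 0.1.0
Authors@R: person("EST-SSR", "Maintainers", email = "estssr@example.org",
    role = c("aut", "cre"))
Description: Toolkit for microsatellite (SSR) analysis in assembled
    transcriptome contigs and for the design of unique EST-SSR markers.
    Detects perfect di- to hexanucleotide repeats under MISA-style minimum
    repeat thresholds, normalizes repeat motifs to canonical classes under
    cyclic rotation and reverse complementation, places loci in 5'UTR,
    coding or 3'UTR context from coding-region coordinates, and runs a
    marker-design pipeline (CMiB) combining greedy sequence clustering,
    SSR-targeted primer design, in-silico PCR triage of unique products,
    amplicon clustering with shortest-product selection, and known-marker
    exclusion. Includes the summary and inferential statistics used in
    EST-SSR surveys: motif-by-location tables, SSR frequency and density,
    GC composition, GO-term enrichment, binomial and Poisson GLMs with
    Wald tests, and marker diversity indices (Na, Ho, He, PIC).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
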