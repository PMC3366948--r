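Package: panelcall
Title: SNV Calling and Benchmarking for Targeted 454-Style Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-nucleotide variant (SNV) detection on targeted
    gene panels sequenced with long-read pyrosequencing chemistry, and for
    benchmarking calling pipelines against validated truth sets. Includes a
    synthetic read simulator for multi-gene capture panels (PCR duplicates,
    multi-mapping reads, homopolymer-associated errors, GC-dependent
    coverage, and discordant placements between two alignment views),
    duplicate removal, pileup construction, a depth/allele-frequency
    threshold caller and a rule-based high-confidence-difference caller, a
    post-calling filter on mapping quality, depth, gap proximity and local
    SNV density, dual-view consensus intersection, gene-model annotation
    (region, coding effect, known-variant filtering, recurrence ranking,
    SNP-cluster and GC-coverage diagnostics), and confusion-matrix metrics
    (sensitivity, specificity, Matthews correlation coefficient) over
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    Rsamtools,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
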