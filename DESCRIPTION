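Package: pavscape
Title: Presence/Absence Variation and Synteny Analysis for Accession Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects presence/absence variation (PAV) and highly diverged
    regions (HDR) between two genome assemblies of the same species by
    reciprocal read mapping: zero-coverage regions on each assembly are
    classified by anchoring their 1 kbp flanks in the read-source assembly
    and validated by mate-pair distance deviations. Also provides
    reciprocal-best-hit (RBH) protein synteny with dot-plot outlier typing,
    scaffold split hints and reference-guided scaffold anchoring with AGP
    output, k-mer based genome-size estimation, read-depth repeat copy
    number, genome-composition reconciliation, and assembly/gene-space
    completeness metrics. A seeded synthetic accession-pair and read
    simulator with a ground-truth variant registry makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
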