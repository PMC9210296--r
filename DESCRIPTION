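Package: hybridmsci
Title: Stage-Specific X Chromosome Misexpression and Ampliconic Copy Number
    in Hybrid Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for stage-resolved testis expression studies of
    hybrid male sterility in house mice. Implements negative-binomial
    differential expression with likelihood-ratio tests for FACS-enriched
    spermatogenic cell populations, X-versus-autosome misexpression asymmetry
    tests, a sliding gene-window Poisson enrichment scan, two relative-coverage
    estimators of ampliconic sex-linked gene-family copy number (region
    coverage and kmer-derived informative sites), sperm phenotype summaries
    with nonparametric tests, and C2H2 zinc-finger allele typing for Prdm9.
    Ships synthetic-data generators that emulate the statistical structure of
    such studies (meiotic sex chromosome inactivation, hybrid de-repression,
    collapsed amplicon read depth) so the full pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
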