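Package: polyfusion
Title: Bottom-Up Discovery and Genotyping of Polymorphic Gene Fusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing population-specific (polymorphic) chimeric
    RNAs back to the structural variants that create them.  The package
    filters chimeric-RNA prediction catalogs for polymorphic candidates,
    genotypes the causal structural variants directly from raw sequencing
    reads by approximate matching of breakpoint-spanning queries followed
    by re-mapping validation, corroborates variants from discordant
    read-pair orientation signatures and coverage profiles, and runs
    population-genetic (allele frequency, Hardy-Weinberg) and
    covariate-adjusted phenotype-association stages.  A synthetic-cohort
    generator builds toy genomes with planted deletions, duplications,
    inversions and complex inversion-deletion alleles, Hardy-Weinberg
    cohorts, paired-end reads with truth alignments, chimera-prediction
    tables and phenotype tables, so the whole pipeline is testable end to
    end without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
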