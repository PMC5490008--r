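Package: virodiv
Title: Viral Population Microdiversity Simulation and Its Impact on
    Metagenomic Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates viral populations with controlled microdiversity
    (SNP-level variants, target average nucleotide identity, hypervariable
    genomic islands) spiked into a synthetic virome, and quantifies the
    downstream consequences: fragment-recruitment abundance statistics
    (KPKG normalization, relative recruitment, identity diversity curves),
    binomial SNP calling from pileups with a normalized SNP-frequency
    statistic, fragment-based average nucleotide identity, in-silico
    tryptic peptide recruitment, droplet-coincidence arithmetic for
    single-virus sorting, and a de Bruijn assembler with a
    provenance-aware evaluator that detects chimeric consensus contigs.
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
    S4Vectors,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'classes-methods.R'
    'align.R'
    'popgen.R'
    'readsim.R'
    'recruit.R'
    'snp.R'
    'assembly.R'
    'peptidome.R'
    'labqc.R'
    'io.R'
    'pipeline.R'
    'utils.R'
    'virodiv-package.R'
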