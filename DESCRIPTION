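Package: casNeighbors
Title: Gene-Neighborhood and CRISPR-Cas Co-Occurrence Analysis for
    CARF/WYL Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for characterizing protein
    superfamilies (such as CARF and WYL) by their genomic context.
    Reads prokaryotic genome annotations (GenBank flat files or NCBI
    PTT tables with protein FASTA), extracts gene neighborhoods around
    query genes, clusters neighbor proteins by single linkage under
    joint length-coverage and score-density (bit score per alignment
    column) thresholds, calls CRISPR-Cas loci from cas-gene signature
    families and assigns system types, quantifies per-family and
    per-genome co-occurrence with CRISPR-Cas systems, classifies domain
    architectures into effector-bearing and regulatory forms, and
    selects one representative genome per genus.  A synthetic-genome
    generator with planted protein families, CRISPR-Cas loci and
    neighborhood associations provides fully ground-truthed collections
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'casNeighbors-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'annotation-io.R'
    'architecture.R'
    'pairwise.R'
    'clustering.R'
    'neighborhood.R'
    'crispr.R'
    'representatives.R'
    'synthetic-data.R'
    'pipeline.R'
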