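Package: brexscan
Title: Detection, Classification and Phyletic Profiling of BREX and
    BREX-Related Anti-Phage Defense Systems
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs candidate BREX (BacteRiophage EXclusion), BR
    (BREX-Related) and BRC (BREX-Related Capture) defense loci from
    annotated prokaryotic genomes, calls their protein components from
    domain architectures, classifies loci into the ten described
    subtypes with a rule-based decision list, catalogs primary,
    auxiliary and backup nuclease effectors, aggregates TaxID-deduplicated
    phyletic presence/absence matrices, and computes dual-alphabet
    (20-letter and reduced 8-letter) positional Shannon entropy profiles
    of protein alignments. Ships a synthetic-cohort generator with
    machine-readable ground truth so the whole pipeline is testable
    without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SequenceMatching, Classification, ComparativeGenomics
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'classify.R'
    'cluster.R'
    'entropy.R'
    'genbank-io.R'
    'neighborhood.R'
    'phyletics.R'
    'pipeline.R'
    'registry.R'
    'synthdata.R'
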