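Package: karyevol
Title: Polyploidization History and Karyotype Evolution from Gene-Order Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs paleopolyploidization histories and ancestral
    karyotype trajectories from gene order. Implements collinear synteny
    block chaining with c-score homolog filtering, Nei-Gojobori synonymous
    divergence (Ks) with Gaussian-mixture peak fitting, syntenic-depth
    ratio analysis with multiplicative decomposition of ploidy levels into
    diploidization and triploidization events, ancestral-karyotype painting
    with classification of chromosome fusions (end-to-end joining, nested
    chromosome fusion) and reciprocal arm translocations, subgenome
    assignment with fractionation and core-orthogroup retention statistics,
    and gene duplication mode classification. Ships a seeded genome
    evolution simulator emitting extant gene orders plus ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'codon.R'
    'evosim.R'
    'synteny.R'
    'ploidy.R'
    'karyotype.R'
    'fractionation.R'
    'genome-io.R'
    'ksdist.R'
    'scenario.R'
    'pipeline.R'
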