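Package: comorbidNet
Title: Comorbid Phenotype Networks and Functionally Coherent Clusters from
    CNV Patient Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds phenotype-phenotype comorbidity networks from patient
    cohorts annotated with ontology-coded phenotypes and copy-number-variant
    (CNV) coordinates. Patient overlap between phenotypes is scored with the
    hypergeometric index (-log10 upper-tail probability) and split into
    more-specific and less-specific pair lists. CNVs are decomposed into
    small overlapping regions (SORs) shared by at least two patients, which
    connect phenotypes to genes; gene sets are tested for functional-system
    over-representation, and pair-level results are classified as consistent
    or emergent. Networks of such pairs are clustered into link communities
    by maximising partition density, filtered for functional coherence, and
    validated against disease annotations, literature co-mention, Resnik
    semantic similarity and patient-level cluster support, with
    degree-preserving, label-permutation and SOR gene-content null models
    throughout. A seeded synthetic-cohort generator with planted modules
    supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, CopyNumberVariation, GeneSetEnrichment,
    Clustering, Phenotype
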