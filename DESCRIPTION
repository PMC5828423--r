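Package: phylogcn
Title: Phylogenetic Hidden-State Prediction and Predictability of 16S rRNA
    Gene Copy Numbers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how predictable a discrete genomic trait,
    such as the 16S rRNA gene copy number (GCN), is from a phylogeny.
    Implements five hidden-state-prediction algorithms (Sankoff maximum
    parsimony under three transition-cost schemes, Mk equal-rates maximum
    likelihood with rerooted marginals, phylogenetic independent contrasts,
    weighted squared-change parsimony, and subtree averaging), the
    phylogenetic trait autocorrelation function, nearest-sequenced-taxon
    distances (NSTD) and indices (NSTI), NSTD-stratified cross-validation,
    tool-agreement analyses across microbial community samples, and GCN-based
    read-count correction. Ships synthetic-data generators (birth-death
    trees, Mk and bounded-walk trait evolution, coverage masking, log-normal
    community profiles) so the whole pipeline runs without reference
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
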