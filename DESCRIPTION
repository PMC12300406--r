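Package: ssrcurate
Title: SSR-Based Curation of Germplasm Collections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating clonally propagated germplasm collections
    genotyped with co-dominant microsatellite (SSR) markers. Provides
    per-locus diversity statistics (allele counts, heterozygosity, fixation
    index, polymorphic information content, probability of identity and
    discrimination power, parentage non-exclusion probabilities, Monte Carlo
    Hardy-Weinberg tests), multilocus fingerprint matching for duplicate,
    synonym, homonym and mislabelling detection with a collection error
    rate, Mendelian verification of declared pedigrees, Lynch band-sharing
    similarity with UPGMA clustering and Newick export, a Bayesian admixture
    model (Gibbs sampler) for population structure with Evanno delta-K model
    selection, and a fully seeded synthetic-collection generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
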