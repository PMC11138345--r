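Package: breedalloc
Title: Optimized Progeny Allocation for Genomic Selection Breeding Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of recurrent genomic-selection breeding
    schemes with softmax allocation of a fixed progeny budget across diallel
    mating pairs. Pair features (breeding value, rare-allele-weighted breeding
    value, and the expected genetic variance of progeny of a cross) are combined
    with per-generation weights, and the weight schedule is tuned with the
    StoSOO stochastic tree-search optimizer to maximize the final genetic gain.
    Includes a founder-genome generator with linkage disequilibrium, k-medoids
    parent-panel selection, Kosambi-map meiosis, strategy-comparison
    experiments, and file formats for crossing tables and weight schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
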