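Package: biparcc
Title: Cross-Kingdom Bipartite Co-Occurrence Networks from Compositional
    Marker-Gene Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed microeukaryote-bacteria co-occurrence bipartite
    networks from paired 16S and 18S OTU count tables and analyses their
    architecture. Implements SparCC compositional correlation inference with
    permutation p-values, prevalence filtering and rarefaction, extraction of
    significant inter-kingdom edges into positive and negative bipartite
    networks, quantitative network topology (connectance, NODF nestedness,
    linkage density, interaction diversity and evenness, Bluethgen's d'
    specialization, guild clustering, compartments), nestedness significance
    against Patefield fixed-marginal null models, Barber bipartite modularity
    via weighted label propagation with restarts, z-c keystone role
    classification, core-taxa degree-symmetry summaries, and co-extinction
    robustness simulation. Includes a synthetic community generator with
    planted inter-kingdom associations for end-to-end validation, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
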