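Package: nanclust
Title: Detection and Evolutionary Analysis of Sialic Acid Catabolism Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sialic acid catabolism (nan) gene clusters in ordered
    bacterial gene annotation tables using domain-evidence role calling and
    genomic-neighborhood rules, and characterises their distribution and
    evolution: per-taxon positive-rate tables with a minimum-count rule,
    habitat-association testing by Fisher's exact test, and Wagner-parsimony
    gain/loss reconstruction of cluster presence on a species tree. Includes
    genome quality filtering, ANI-based dereplication, and a seed-reproducible
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
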