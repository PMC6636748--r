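Package: cardigan
Title: Disease Gene Prioritization for Charted and Uncharted Diseases by
    Network Propagation of Phenotype-Similarity Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by propagating
    phenotype-similarity-derived seed weights over a protein-protein
    interaction network. A query disease is seeded with weight 1 on its own
    known genes and with sigmoid-dampened semantic (Resnik-family) phenotype
    similarity on the genes of other diseases; the seed vector is then
    diffused with the Zhou et al. label-consistency method (closed form
    F = beta * (I - alpha * S)^-1 Y over the degree-normalized adjacency S).
    Because seeds can be built purely from phenotype annotations, predictions
    are available even for molecularly uncharacterized ("uncharted")
    diseases. Includes ontology-based disease similarity (information
    content of the most informative common ancestor), leave-one-out,
    time-lapse and disease-module-reconstruction evaluation protocols with
    recall at k and truncated normalized ROC AUC, random baselines, and a
    planted-partition synthetic-benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
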