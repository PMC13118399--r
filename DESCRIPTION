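Package: aggrekey
Title: Soil Aggregate Stability and Keystone Microbial Modules in Intercropping Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wet-sieved soil aggregate data and
    multi-kingdom amplicon genus tables from replicated cropping-system
    trials. Computes aggregate stability metrics (mean weight diameter,
    R0.25 mass and carbon fractions), aggregate-associated carbon
    accounting with Duncan multiple-range letters, community ordination
    (Bray-Curtis, PCoA, PERMANOVA), Spearman co-occurrence networks with
    walktrap module detection, keystone module and genus selection,
    permutation-importance ranking of genera against aggregate-carbon
    responses, and a partial least squares path model linking microbial
    abundance to aggregate stability. Includes a synthetic-data generator
    that plants correlated genus modules coupled to macroaggregate carbon
    so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), mclust
Config/testthat/edition: 3
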