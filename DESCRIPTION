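Package: benthicnet
Title: Co-Occurrence Social Diversity in Benthic Transect Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds species co-occurrence networks from per-centimetre
    benthic transect records and quantifies co-occurrence social diversity
    with exponential random graph models. Provides run-length encoding of
    transect observations, network construction with size and run-count
    vertex covariates, ERGM sufficient and change statistics (edges,
    fixed-decay geometrically weighted edgewise shared partners, vertex
    covariates and species factors), exact small-graph likelihoods,
    maximum pseudolikelihood, Metropolis-Hastings simulation and
    Monte-Carlo maximum likelihood, simulation-based goodness of fit with
    degeneracy diagnostics and a covariate-model fallback, cross-survey
    aggregation into species, phylum and site summaries, random-forest
    relative influence of survey factors, and a synthetic transect
    generator with planted affinities and triad propensities for
    ground-truthed validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
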