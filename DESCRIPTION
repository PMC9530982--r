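Package: confnet
Title: Confidant Network Construction and Depressive-Symptom Homophily
    Analysis for Community Surveys of Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds directed confidant networks from community survey
    records of older adults (household listings plus name-based community
    nominations matched under strict identification criteria), scores the
    15-item Geriatric Depression Scale with its apathy and suicidal-ideation
    subscales, computes directed-network descriptive statistics, and
    estimates attribute homophily with a directed exponential random graph
    model restricted to dyad-separable terms (edges, reciprocity, nodal
    main effects, absolute-difference similarity). Because every term is
    dyad-separable the likelihood factorises over dyad states, giving an
    exact maximum-likelihood estimator alongside maximum pseudolikelihood,
    Metropolis-Hastings network simulation and Monte-Carlo MLE. A synthetic
    community generator emits survey tables with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
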