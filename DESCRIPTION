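Package: socialsim
Title: Simulation and Genetic Analysis of Directional Social Interactions in Group-Housed Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates directional social interactions (e.g. feather pecking,
    tail biting) between group-housed animals and estimates genetic parameters
    and breeding values from the resulting records. Each animal carries two
    latent logit-scale traits, a performer and a recipient tendency, with a
    pedigree-structured bivariate genetic architecture and permanent
    environmental effects. An agent-based model moves animals through pens
    (eat/walk/rest motivation dynamics, feeders, sensing range) to generate
    encounters, and encounters are turned into binary directed interaction
    events through a logistic latent-trait model. Inference tools include a
    pedigree animal-model REML for calibrating observed-scale heritability of
    interaction counts, a penalized quasi-likelihood binomial logit mixed model
    with Kronecker pedigree covariance for performer/recipient effects, and
    selection-index accuracy bounds for evaluating estimated breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
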