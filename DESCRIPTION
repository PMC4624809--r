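Package: accumaint
Title: Evidence Accumulation and Choice Maintenance in Perceptual Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of two-alternative
    forced-choice perceptual decision experiments with immediate (reaction-time)
    and delayed response modes. Provides a drift-diffusion trial simulator and a
    hierarchical drift-diffusion model with a Wiener first-passage-time
    likelihood, model comparison by the deviance information criterion and
    posterior predictive checks; hierarchical gamma response-time and
    beta-binomial accuracy models fit by Gibbs sampling, with grouped chains,
    posterior difference probabilities, highest-density intervals and
    Gelman-Rubin diagnostics; forward BOLD predictions from hypothesized
    decision-neuron firing profiles convolved with the canonical double-gamma
    hemodynamic response function; and a coordinate-based reverse-inference
    meta-analysis toolkit (term databases, activation-foci databases, posterior
    probability and posterior-z maps, local maxima, ROI-weighted evidence
    scores). A synthetic-data module generates every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
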