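Package: msrl
Title: Multisensory Reward Learning with Subspace Generalization Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interactive single-step reward-maximization framework for
    multisensory decision making.  An agent maintains incremental reward
    statistics in the joint sensory space and in all of its marginal
    subspaces, screens each subspace with an interval-intersection
    generalization test that separates beneficial perceptual aliasing from
    harmful ("garbage") aliasing, and selects actions through
    confidence-interval policies (most-optimistic-source and
    least-uncertain-source selection).  Includes a discrete audiovisual
    localization simulator with Gaussian and uniform-noise sensors, a
    reliability-weighted Bayesian observer and UCB1 baselines, and
    experiment drivers that reproduce the emergent developmental transition
    from sensory selection to sensory integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
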