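Package: trapjawkit
Title: Comparative Phylogenetics and Biomechanics of Trap-Jaw Mandible Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying repeated evolution of latch-mediated
    spring-actuated (trap-jaw) mandibles on dated phylogenies. Implements
    Mk-model likelihoods by Felsenstein pruning with ML fitting and AICc
    comparison, marginal ancestral states, stochastic character mapping via
    endpoint-conditioned CTMC path sampling (uniformization), strike
    kinematics from digitized angle traces (spline smoothing, thin-rod
    kinetic energy, mass-specific power, power-amplification calls),
    generalized Procrustes analysis with tangent-space PCA of 3D landmark
    configurations, linear mandible measurements, branchwise
    quartet-informative locus audits for presence/absence matrices, and
    synthetic-data generators with exact ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vegan,
    cluster,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
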