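Package: coneSpec
Title: Stochastic Simulation of Thyroid-Hormone-Gated Cone Photoreceptor
    Specification in Retinal Organoids
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hybrid deterministic-stochastic simulator of cone photoreceptor
    subtype specification in human retinal organoids. Retinal progenitor cells
    (RPCs) differentiate into immature S or L/M cones at thyroid-hormone (T3)
    dependent rates and into non-cone fates at a constant rate; RPCs express
    the T3-degrading enzyme DIO3, so T3 rises as the progenitor pool shrinks,
    timing the sequential generation of S and then L/M cones ("hourglass"
    feedback). Cell-fate events are sampled with the Gillespie algorithm while
    the T3 concentration is integrated deterministically. The package includes
    a constant-rate cell-intrinsic comparator model, replicate experiments that
    quantify the noise filtering of initial progenitor abundance (coefficient
    of variation of final photoreceptor counts), log-uniform parameter-space
    robustness sweeps, condition presets for DIO3-mutant and exogenous-T3
    organoids, and a generator of synthetic opsin-density time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'coneSpec-package.R'
    'intrinsic.R'
    'rates.R'
    'simulate.R'
    'experiments.R'
    'io.R'
    'observables.R'
    'observations.R'
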