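Package: egrowth
Title: Elementary Growth Modes and Vectors for Self-Fabricating Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact enumeration and analysis of elementary growth modes (EGMs)
    and elementary growth vectors (EGVs) in next-generation (self-fabricating)
    metabolic models, where macromolecule synthesis is explicit and biomass
    composition is an outcome rather than an input.  Provides a
    polyhedral-geometry core over exact rational arithmetic (elementary
    vectors of s-cones, general polyhedral cones and polyhedra; conformal
    decomposition), growth-cone and growth-polyhedron construction with
    catalytic capacity and membrane constraints, autocatalysis and
    kinetic-consistency classification including minimal autocatalytic (MAC)
    reaction sets, growth-rate sweeps with detection of regime transitions,
    and a comparison construction for traditional biomass-reaction models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
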