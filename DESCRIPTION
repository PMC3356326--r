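Package: dynpet
Title: Dynamic PET Kinetic Quantification with Logan Graphical Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification tools for 60-minute small-animal
    dynamic PET studies of reversible tracers. Provides a reversible
    two-tissue compartment simulator with a Feng-type arterial input
    function, digital phantoms with known ground truth, VOI construction
    with a fractional-maximum voxel screen, time-activity curve extraction
    and percent injected dose per gram normalization, Logan graphical
    analysis with plasma and reference-tissue inputs (total distribution
    volume, distribution volume ratio, binding potential, and the
    specific/non-displaceable decomposition), voxel-wise parametric
    V_T and Bp_ND mapping, and group-level comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    RNifti,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
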