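Package: orthosim
Title: Quasistatic Soft-Tissue Finite-Element Simulation for Orthognathic
    Surgical Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tetrahedral Neo-Hookean finite-element simulation of facial soft
    tissue driven by prescribed rigid bone-fragment transforms, for
    computational planning of orthognathic (jaw) surgery. Provides fixed and
    bonded coupling of tissue to bone through selection matrices, smooth
    linear-blend-skinning coupling across osteotomy cuts, penalty sliding
    contact against signed distance fields, a reduced Newton solver with
    substepped transform trajectories, synthetic slab-and-block test scenes,
    and a validation toolkit with iterative-closest-point rigid registration,
    signed closest-point error maps and cumulative error-threshold summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
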