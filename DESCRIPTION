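Package: tissuetectonics
Title: Tissue-Tectonics Strain Maps from 3D Cell Tracks on a Spherical Embryo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whole-embryo tissue kinematics from tracked nuclei on a
    spherical (gastrula-stage) embryo surface. Cell tracks are grouped into
    overlapping spherical domains around the nodes of a near-uniform mesh; a
    3x3 velocity-gradient tensor is estimated per domain by weighted affine
    regression and decomposed into strain-rate (symmetric) and spin
    (antisymmetric) parts. Strain-rate components along the anterior-posterior,
    medio-lateral and radial anatomical directions, the trace (divergence) and
    the radial curl are integrated over sliding time windows to give strain
    maps and angle-by-time kymographs along equatorial and axial bands. A
    synthetic-embryo simulator with composable analytic flows (epiboly,
    convergence, extension, rigid rotation, radial expansion) and closed-form
    velocity gradients provides ground truth for validation, including a Wnt
    inhibition (no-extension) scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
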