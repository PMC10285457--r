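Package: wallstrain
Title: Fast 2D Strain Mapping of the Aneurysm Wall from B-Mode Ultrasound Cine-Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic strain mapping in the abdominal aortic aneurysm
    (AAA) wall from transverse B-mode ultrasound cine-loops. From manually
    placed inner-wall landmarks and a multi-frame grayscale sequence, the
    package builds a 2-mm wall region of interest, automatically selects
    high-gradient tracking points, tracks wall motion per pressure cycle with
    a demons-style sparse tracker (forward/backward merged), and maps
    circumferential, radial and shear strains by cubic radial-basis-function
    interpolation with analytic differentiation. Two validation instruments
    are included: a scatterer-based B-mode speckle simulator of a pulsating
    annular vessel wall with known ground-truth motion, and a bilinear
    reduced-integration finite-element strain oracle for cross-validation and
    mesh-convergence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
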