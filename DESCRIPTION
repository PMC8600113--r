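Package: plaquestress
Title: Cyclic Plaque Structural Stress from Intravascular Imaging Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the change in coronary plaque structural stress over the
    cardiac cycle from cross-sectional vessel geometry and intracoronary
    pressure recordings. Builds layered (intima/media/adventitia) multi-material
    geometric models from lumen and internal-elastic-lamina contours, derives
    position-specific cyclic pressure loads from aortic and distal pressure
    tracings normalized along a pressure-ratio pullback curve, and solves the
    2D plane-strain large-deformation hyperelastic equilibrium (Mooney-Rivlin
    and Holzapfel-type materials, follower pressure loading) with a built-in
    finite-element solver. Reports the cyclic change in plaque structural
    stress, lumen diameter change, plaque burden and fibrous cap thickness per
    cross-section, and includes a synthetic cross-section and pressure
    generator so the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
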