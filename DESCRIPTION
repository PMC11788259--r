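Package: oact
Title: Optical Contour Tracing for Electron Cutout Fabrication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs a physician-drawn skin-marking contour in three
    dimensions from two photographs taken at known heights inside an electron
    applicator, projects it with per-point magnification to the electron
    cutout plane (typically 95 cm from the source), and scores traced
    contours against references with the area ratio index (ARI) and the
    contour matching index (CMI). Includes a synthetic scene generator and
    pinhole renderer so the full pipeline can be validated without hardware,
    plus CSV/SVG/JSON export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
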