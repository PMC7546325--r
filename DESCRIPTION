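Package: stomapore
Title: Automated Stomata Detection and Pore Area Measurement in Leaf Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing stomata in brightfield
    micrographs of leaf-surface imprints, such as whole-slide scanner images.
    Large scans are tiled and screened with a sliding-window patch classifier
    (gradient-orientation-histogram features and a quadratic-kernel support
    vector machine) trained on stomate, vein and background patches. Each
    detected stomate is measured with a polarity-robust pore-area algorithm:
    local contrast enhancement, Otsu binarisation, connected-component
    selection, major-axis alignment, and a cross-section peak/valley analysis
    that locates the pore centre whether the pore is darker or lighter than
    the surrounding guard cells, followed by tolerance-based region growing.
    Includes grid-discretised detection scoring, pore-accuracy bookkeeping,
    and a seeded synthetic micrograph generator with exact ground-truth masks
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
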