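Package: flowcolonize
Title: Advection-Diffusion Modelling and Image Quantification of Bacterial
    Surface Colonization Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how fluid flow and swimming motility shape early
    bacterial surface colonization in microchannels. Provides channel
    geometry and Peclet-number calculations, a Brownian-dynamics simulator of
    planktonic cell transport with a partially absorbing floor, an
    agent-based simulator of asymmetrically dividing surface populations with
    two fluorescent lineages, a synthetic two-channel fluorescence image
    generator with ground-truth masks, and the full quantification pipeline
    (adaptive-threshold segmentation, surface coverage, microcolony areas,
    cross-lineage mixing distances, attachment-event detection, and
    attachment-probability scaling fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
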