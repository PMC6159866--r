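Package: leafwet
Title: Seasonal Leaf Wettability from Hierarchical Wetting Models and
    Micrograph Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the wettability of plant leaves whose surfaces carry a
    two-tier roughness: microscale papillose epidermal bumps and nanoscale
    epicuticular wax tubules. Implements a combined Wenzel and Cassie-Baxter
    apparent contact-angle model with an intact-wax areal fraction, predicted
    contact-angle hysteresis, meniscus penetration between wax tubules,
    spherical-cap droplet geometry, and the tilted-plate force balance giving
    critical droplet volumes and roll-off angles. Provides morphometry
    estimators that extract the model parameters (microscale roughness, wax-tip
    contact fraction, intact-wax fraction) from calibrated grayscale electron
    micrographs, plus seeded synthetic-image generators with known ground truth
    so the whole pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
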