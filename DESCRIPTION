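Package: mealvision
Title: Two-View Food Volume Estimation and Nutrient Assessment
Version: 0.1.0
Authors@R: person("mealvision", "developers", role = c("aut", "cre"),
    email = "mealvision@example.org")
Description: Desk-scale implementation of an image-based dietary assessment
    pipeline: metric camera pose recovery from a credit-card-sized reference
    object aided by an IMU gravity vector, two-view dense stereo matching and
    triangulation, table-plane fitting, food volume integration, seeded
    region-growing segmentation, three-level hierarchical food recognition
    with weighted inference, and per-100-ml macronutrient computation. A
    built-in synthetic scene generator with analytic ground-truth volumes
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
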