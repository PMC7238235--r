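Package: tabscale
Title: Scaling Tableting Processes Between Rotary Presses and Compaction
    Simulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transferring tableting processes between rotary tablet
    presses and single-station compaction simulators. Simulates punch
    displacement profiles from geometric machine data (turret pitch circle,
    compression roller, punch head flat), extracts dwell time, compression
    time, stress prolongation and residual punch velocity from compaction
    profiles, computes feed-frame shear numbers for rotary presses and their
    compaction-simulator-adapted form, solves for the paddle-wheel frequency
    that matches a rotary press's powder shear history, and provides tablet
    property calculations (diametral tensile strength, porosity,
    tabletability curves). Includes a synthetic-data generator emulating
    simulator-specific profile deviations and the tensile-strength response
    of lubricated powder blends to shear exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
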