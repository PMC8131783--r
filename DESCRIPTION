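Package: bearcond
Title: Scat-Based Diet Quantification and Photogrammetric Body Condition
    of Brown Bears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying brown-bear diet from scat samples
    (point-frame occupancy, digestibility-corrected estimated dietary
    content and digestible-energy content, through-origin calibration of
    visual volume estimates, high/low consumption year classification),
    for deriving a photograph-based body-condition index (the ratio of
    torso height to horizontal torso length measured on rectified
    lateral photographs), and for modelling seasonal body-condition
    trajectories with gamma generalized additive mixed models with
    factor-by smooths, crossed random intercepts, and AICc-based
    multimodel selection. Includes a synthetic-study generator with
    known ground truth so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
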