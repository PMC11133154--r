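Package: scrollgaze
Title: Map Eye-Tracking Data from Scrollable Pages to Full-Page Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministically remaps screen-coordinate gaze and fixation data
    recorded while a participant browses a scrollable page onto the coordinate
    system of a full-page stimulus image. Mouse-wheel events embedded in the
    session log drive a clamped viewport-offset state machine; screen
    calibration is recovered from a marker screenshot or supplied manually;
    fixed screen regions (menus, sidebars) are redirected to designated regions
    of the full-page image via bundles of areas with activation rules; display
    input lag is modeled from the monitor refresh rate. Includes a Gaussian
    heatmap overlay renderer and a synthetic-session generator with known
    ground truth so that every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    png,
    EBImage,
    ggplot2,
    generics,
    optparse,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
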