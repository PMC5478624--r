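Package: seedbed3d
Title: Depth-Camera Characterization of Cultivated Seedbed Surface Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Metric 3D reconstruction of cultivated seedbed surfaces from
    single-frame structured-light depth images (Kinect-class sensors),
    decomposition of the reconstructed surface into a basal soil surface and
    protruding soil blocks (clods), per-clod measurement and size-class
    binning, ISO 25178-2 areal height parameters (Sa, Sq, Ssk, Sku),
    classification into ten tilth grades, and calibration/validation
    statistics (R squared, RMSE, REP) against manual reference measurements.
    Includes a synthetic seedbed simulator with full ground truth so the
    entire pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deldir,
    digest,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
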