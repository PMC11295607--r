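Package: osteonav
Title: Rigid Registration and Cutting-Plane Accuracy Evaluation for
    Tracker-Less Osteotomy Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for image-guided high tibial osteotomy navigation studies:
    closed-form (SVD) paired-point rigid registration, iterative closest point
    (ICP) surface matching and the two-stage (point + surface) registration
    procedure; fiducial and target registration error metrics; planned versus
    achieved cutting-plane accuracy as projected angle differences in the XZ
    and YZ coordinate planes; readers and writers for STL/PLY meshes, landmark
    CSV files and plane/transform JSON; a synthetic tibia generator and a
    Monte-Carlo sawbone-trial harness comparing guidance modalities
    (metal jig, conventional navigation, tracker-less AR), with a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
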