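Package: ccpbrm
Title: Simulation, Detection and Evaluation Toolkit for Circular
    Crossed-Polarized Birefringence Microscopy of Myelin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated myelin-defect detection in volumetric
    circular crossed-polarized birefringence microscopy (CCP-BRM)
    z-stacks. Provides a Jones-calculus forward model of RGB CCP-BRM
    image formation and a synthetic phantom generator with exact
    ground truth; TIFF z-stack and YOLO/JSON annotation I/O with
    sliding-window extraction; a detector-agnostic volumetric
    inference engine with per-plane non-maximum suppression, z-plane
    vesicle filtering and defect-density heatmaps; a human-in-the-loop
    pseudo-labeling workflow (proposal export, expert review
    ingestion, cumulative dataset assembly); and an evaluation layer
    with consensus ground truth, precision/recall/F1,
    class-frequency-weighted mAP@50, intraclass correlation and
    pairwise Pearson reliability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
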