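Package: SubsideOCT
Title: Detection of Outer Plexiform Layer Subsidence in Retinal OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage detection of outer plexiform layer (OPL) subsidence,
    an early optical coherence tomography (OCT) biomarker of progression
    towards geographic atrophy, in macular OCT volumes. A per-B-scan
    detection module proposes candidate bounding boxes with confidences, a
    per-B-scan classification module scores subsidence presence, the two are
    fused multiplicatively, and overlapping candidates on adjacent B-scans
    are merged into scored 3D cuboids. Includes a synthetic layered-retina
    volume generator with exact ground truth, the full evaluation protocol
    (FROC, ROC/AUC, precision-recall/AP, hierarchical volume/eye/participant
    aggregation, stratified participant-level cross-validation), and
    readers/writers for volumes (multi-page TIFF, NIfTI), A-scan annotations
    and detections (JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
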