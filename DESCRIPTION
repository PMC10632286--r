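Package: osteoplanr
Title: Automatic Osteotomy Planning for Deformed Forearm Bones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic three-dimensional planning of corrective wedge
    osteotomies of the radius and ulna. The deformed bone is compared against
    the mirrored healthy contralateral bone: joint-end fragments are isolated
    and rigidly registered by iterative closest point, a cutting plane
    parametrized by a centerline station and two transverse tilts is optimized
    by exhaustive grid search, and the resulting realignment is decomposed into
    translations and Euler angles. Includes segmentation-agreement metrics
    (Dice, mean absolute surface distance, Hausdorff and 95th-percentile
    Hausdorff distance), relative cartilage volume, study-level statistics
    (intraclass correlation, paired tests, exponential cartilage-age fits),
    and a synthetic bone-phantom generator with planted wedge deformities for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
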