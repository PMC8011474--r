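Package: darcsrf
Title: Longitudinal Prediction of Subretinal Fluid from Retinal Apoptosis Spot Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline linking en-face DARC (Detection of Apoptosing
    Retinal Cells) spot imaging to the later development of subretinal fluid
    (SRF) on OCT in age-related macular degeneration. Provides a synthetic
    longitudinal cohort generator with known ground truth, fiducial-based
    affine and B-spline non-rigid registration of en-face images to OCT volume
    coordinates, template-matching spot detection with non-maximum suppression
    and baseline autofluorescence subtraction, per-interval SRF quantification
    with new-SRF/conversion rules, unique-spot prediction with per-interval
    confusion matrices and predictive metrics, SRF-free survival by DARC-count
    group, and exact small-sample statistics (Cohen's kappa, Spearman,
    Mann-Whitney, Wilcoxon signed-rank, regression slope comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
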