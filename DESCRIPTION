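Package: echoSimpson
Title: Simpson's Method-of-Disks Ejection Fraction Estimation from
    Left-Ventricle Segmentation Masks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clinically aligned estimation of left-ventricular ejection
    fraction (LVEF) from binary left-ventricle segmentation masks of
    end-diastolic and end-systolic apical four-chamber frames.  Extracts
    Simpson's method-of-disks features from a mask (contour, apex and
    mitral-valve landmarks, major axis, per-disk diameters), computes
    monoplane and biplane method-of-disks volumes and the ejection
    fraction, and estimates LVEF by regression on the extracted disk
    features with grid-search cross-validation.  Includes the standard
    segmentation and agreement metrics (Dice, Hausdorff, contour mean
    absolute error, Pearson correlation, Bland-Altman limits of
    agreement) and a synthetic left-ventricle generator with closed-form
    volumes that provides exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    EBImage,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'io.R'
    'geometry.R'
    'volumetrics.R'
    'metrics.R'
    'regression.R'
    'nnets.R'
    'cli.R'
    'echoSimpson-package.R'
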