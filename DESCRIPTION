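Package: adadetect
Title: Certified Shortcut Detectives for Acquisition-Dependent Image Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audits binary-labeled image datasets (chest radiographs and
    similar grayscale imagery) for intrinsic acquisition-dependent shortcuts:
    global contrast and sharpness differences that correlate with class labels
    and let classifiers cheat. Provides controllable contrast (gamma) and
    sharpness (Gaussian blur / unsharp mask) perturbations, construction of
    shortcut training sets from disease-free images, ensemble "shortcut
    detective" classifiers with a fast feature-based backend and a small
    reference convolutional network, a two-exam certification protocol
    (chance-level AUC on shortcut-free data, extreme AUC on known-injected
    data), deployment scans with stratified-bootstrap AUC confidence
    intervals, and a procedural radiograph phantom generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
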