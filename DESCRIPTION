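Package: cusweep
Title: Standard-View Extraction and Severity Screening from Cranial
    Ultrasound Sweep Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Perception-agnostic re-implementation of the screening logic
    used to read neonatal cranial ultrasound sweep videos: per-frame rotated
    bounding-box detection streams are scored against anatomical criteria,
    candidate frames are clustered with DBSCAN to infer the sweep direction
    and reject spurious frames, and one standard view per canonical plane is
    selected. A rule-based ensemble turns per-image multi-label lesion
    probabilities and a case-level severity probability into a severe /
    non-severe verdict following the Papile-based severity convention.
    Includes the matching evaluation metrics (sensitivity, specificity,
    predictive values, F1, ROC AUC, Clopper-Pearson and bootstrap intervals,
    rotated-box mean average precision), reader-trial statistics (Bang's
    blinding index, Cohen's and Fleiss' kappa, two-proportion comparisons,
    Welch t, Wilcoxon signed-rank, Benjamini-Hochberg), and seeded
    generators of synthetic sweep streams and diagnostic cohorts with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
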