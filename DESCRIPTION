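Package: epizmap
Title: Multimodal Normative Abnormality Mapping for Epilepsy Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normative modelling pipeline for temporal lobe epilepsy
    surgery evaluation. Builds harmonized, covariate-adjusted normative
    maps of regional gray-matter volume, superficial-white-matter mean
    diffusivity, and interictal intracranial-EEG relative band power;
    z-scores patients against them; identifies patient-specific abnormal
    regions by ranking and Bayesian change-point thresholding; scores
    overlap of abnormal regions with the surgical resection; and tests
    whether that overlap differentiates seizure outcome (AUC, AUPRC,
    one-tailed rank-sum, DeLong paired ROC, colocalization logistic
    regression). Includes a synthetic cohort generator with planted
    ground truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    sva
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
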