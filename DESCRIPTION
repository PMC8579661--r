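Package: wdcfinger
Title: Individual Connectivity Fingerprints from Resting-State fMRI Degree Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise weighted degree-centrality (wDC) maps from
    preprocessed resting-state fMRI time series, compares individual patients
    against a small normative sample with Crawford's modified t-test,
    binarizes temporal-lobe regions of interest into "increased connectivity"
    indicators, and models post-surgical seizure freedom with backward-stepwise
    logistic regression including calibration, pseudo-R2 and ROC summaries.
    Group-level voxel-wise comparisons use permutation-based cluster-extent
    inference. A synthetic-cohort generator with planted connectivity hubs and
    a known outcome model provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
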