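Package: wmref
Title: White-Matter Reference-Region Optimization for Dynamic Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for optimizing a white-matter reference region for
    reference-tissue quantification of dynamic brain PET, motivated by
    synaptic density (SV2A) imaging. Implements volume-targeted white-matter
    ROI generation by binarize-smooth-threshold, one-tissue-compartment
    volume-of-distribution (VT) estimation from an arterial input function,
    distribution volume ratios (DVR), signed test-retest variability (TRV)
    statistics, interscan-interval regression, case-control group comparison
    (t, Cohen's d, percent difference), and a sample-size calculator. A
    synthetic dynamic-PET phantom generator (brain-like parcellation,
    Gaussian point-spread spill-in, count-like frame noise, test-retest and
    case-control cohorts) exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
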