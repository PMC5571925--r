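Package: petsarc
Title: Quantitative FDG-PET Radiomics and Prognostic Screening for Pediatric Bone Sarcomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative analysis of paired FDG-PET studies in
    pediatric bone sarcoma: adaptive-threshold lesion segmentation,
    intensity metrics (SUVmax, SUVpeak, SUVmean, metabolic tumor volume,
    total lesion glycolysis), 3-D grey-level co-occurrence, run-length and
    size-zone texture features, shape features (elongation, sphericity,
    compactness), PERCIST-style metabolic response classification, and Cox
    proportional-hazards prognostic screening against progression-free and
    overall survival. Ships a synthetic phantom and cohort generator so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
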