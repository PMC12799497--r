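Package: vfscreen
Title: Opportunistic Vertebral Fracture Screening from Chest/Abdominal CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for opportunistic screening of vertebral fragility
    fractures on routine chest and abdominal CT. Reads axial DICOM series
    into calibrated Hounsfield-unit volumes, reconstructs sagittal
    central-slab (CSR) images by summing a fixed-width stack of sagittal
    slices centred on the mid-spine plane, standardizes images for a
    pluggable fracture detector, applies two-step confidence thresholding
    with non-maximum suppression to produce case-level calls, and
    evaluates case-level diagnostic performance (sensitivity, specificity,
    accuracy with continuity-corrected Wilson score intervals, subgroup
    and fracture-mimic breakdowns). A synthetic spine-phantom generator
    with exactly computable ground truth and a stochastic oracle detector
    make the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
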