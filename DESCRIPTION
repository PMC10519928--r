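Package: boneheal
Title: Mechanical and Imaging Monitoring of Critical-Size Bone Defect Regeneration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for instrumented monitoring of critical-size
    bone-defect regeneration under an external fixator. Implements the
    bone-fixator spring-network force-partition model (internal, fixator and
    callus forces; apparent callus stiffness), ground-reaction-force gait
    processing with constant-ratio internal-force calibration, phantom
    calibrated CT morphometry (cross-sectional area, total volume, bone
    mineral density, contralateral normalization), time-course statistics
    (load-share crossover, stabilization, recovery-curve fits, GRF-BMD
    regression), and a forward simulator that generates a synthetic healing
    cohort with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
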