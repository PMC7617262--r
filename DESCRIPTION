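Package: neorelax
Title: Neonatal Brain Relaxometry at 7 Tesla by Simulation-Based T1 and T2 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measurement chain for quantitative T1 and T2 mapping of the
    neonatal brain at ultrahigh field, implemented as a tested simulation and
    estimation pipeline. Includes inversion-recovery T1 fitting with an
    inversion-inefficiency term, isochromat Bloch simulation of slice-selective
    turbo-spin-echo trains, dictionary-based T2 estimation with transmit-field
    (B1) correction from dual-TR actual flip-angle imaging, region-of-interest
    summarisation after label erosion, and random-intercept mixed-effects
    models of relaxation time versus postmenstrual age. A synthetic
    digital-phantom and cohort generator with known ground truth drives
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    minpack.lm,
    EBImage,
    RNifti,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
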