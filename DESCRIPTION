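Package: cervifem
Title: Patient-Specific Finite-Element Safety Assessment of Cervical Spine Fixation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for evaluating the safety of anterior cervical
    discectomy and fusion (ACDF) instrumentation with patient-specific bone
    quality. Generates a parametric synthetic C2-T2 spine phantom with
    intervertebral discs, tension-only ligament trusses and a plate/screw/spacer
    construct, maps per-region bone mineral density to elastic moduli through a
    density-modulus power law, builds head-weight and isometric-strength-derived
    motion load cases, solves linear elastostatics with tied/coupled constraints
    and small-sliding penalty contact, and evaluates fixation safety with a
    principal-strain damage index and segmental range-of-motion measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
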