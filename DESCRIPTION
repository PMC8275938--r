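Package: headcrit
Title: Head Injury Criteria for Vulnerable Road User Impact Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes kinematics-based head injury criteria (HIC15, RIC,
    GAMBIT, HIP, BrIC) from head centre-of-gravity time histories and
    brain-deformation criteria (MPS, CSDM, DDM) from finite-element
    strain and pressure field histories, maps criterion values through
    configurable injury-risk curves, and evaluates predictive
    effectiveness against AIS/MAIS injury records via Pearson
    correlation. Ships the accident-case, injury-score and criterion
    tables of a 31-case vulnerable-road-user impact cohort together
    with synthetic generators for crash pulses, element fields and
    criterion-injury cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
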