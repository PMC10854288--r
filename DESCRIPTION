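Package: qdgraft
Title: Kinematic Analysis of Repetitive Alternating Finger Tapping for
    Parkinsonian Motor Signs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts validated kinematic metrics of Parkinsonian motor signs
    (bradykinesia, rigidity, tremor, arrhythmicity) from 30-second repetitive
    alternating finger tapping (RAFT) displacement traces recorded on a
    quantitative digitography (QDG) device. Detects press/release strike
    cycles, computes eight per-hand kinematic metrics, classifies tremor
    strikes, and scores sessions against an age-adjusted healthy-control
    normative reference via the QDG Mobility Score and Tremor Severity Score.
    Includes a calibrated synthetic trace simulator with ground-truth
    annotations, compliance and medication-adherence reporting, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
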