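Package: notchgr
Title: Multiscale Arterial Growth and Remodeling with Mechano-Sensitive
    Notch Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growth and remodeling (G&R) of a thin-walled artery
    with a constrained mixture model of elastin, collagen and smooth muscle
    cells (SMCs), coupled bidirectionally to a juxtacrine Notch-Jagged-Delta
    signaling model on a one-dimensional radial array of SMCs. Constituent
    turnover is driven by a combination of phenomenological stress and wall
    shear stimuli and a mechanistic Notch stimulus in which circumferential
    SMC strain modulates Notch and Jagged production. Ships parameter presets
    for the murine infrarenal abdominal aorta, hypertension scenarios under
    two intramural stress hypotheses, model-variant switches, and
    interventions with external soluble or immobilized Jagged ligands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
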