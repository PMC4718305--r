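Package: fentapca
Title: Deterministic Pharmacokinetic Simulation of Fentanyl Patient-Controlled Analgesia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven deterministic simulation of intravenous fentanyl dosing
    with a linear three-compartment mammillary pharmacokinetic model and a
    first-order effect-site compartment. Represents dosing programs as timed
    boluses, piecewise-constant infusions and patient-controlled analgesia (PCA)
    demand/lockout schedules, propagates the system exactly between dose events
    with a matrix exponential, computes therapeutic-window compliance metrics
    (minimal-effective-concentration crossing times, undertreated intervals,
    peaks), and searches candidate basal step-down schedules for the
    minimal-exposure regimen that keeps the effect-site concentration inside the
    therapeutic window. Ships the two postoperative-analgesia study scenarios
    (demand-only PCA versus model-based PCA with a tapered basal infusion) as
    built-ins, with JSON regimen configs, CSV series output and a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
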