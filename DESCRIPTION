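Package: hergate
Title: Six-State Gating Model and Voltage-Clamp Analysis for hERG1 Channel Activators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of hERG1 (Kv11.1) potassium channel gating
    and its modulation by activator compounds such as RPR260243. Implements a
    six-state sequential gating model (four independent voltage-sensor
    transitions followed by a concerted opening step) with closed-form voltage
    dependence, a Q-matrix kinetic simulator of step voltage-clamp protocols
    consistent with that model, nonlinear least-squares fitting of Boltzmann,
    double-Boltzmann, logistic (Hill) concentration-response and
    multi-exponential tail-current models with F-test model-order selection,
    tail-current measurement operators including the tail-ratio deactivation
    statistic, and seeded synthetic-data generators emulating two-electrode
    voltage-clamp experiments on wild-type, split, N-/C-terminal deleted and
    D540K hERG1a channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
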