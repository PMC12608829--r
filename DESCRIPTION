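Package: ureakin
Title: Steady-State Kinetic Modelling of pH-Based Enzymatic Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simplified steady-state kinetic model of pH-sensitive
    potentiometric enzyme biosensors (urease/urea on a capacitive
    field-effect transducer). Solves the implicit acid-base/transport
    balance linking bulk substrate concentration to surface pH, recovers
    the apparent Michaelis-Menten constant and normalized maximum rate
    from calibration curves by bounded Nelder-Mead and differential
    evolution, reduces raw constant-capacitance voltage traces to
    calibration points, cross-checks fits with classical linearization
    estimators (Lineweaver-Burk, Eadie-Hofstee, Hanes-Woolf), and
    generates synthetic calibration data for recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
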