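Package: ardsim
Title: Multi-Compartment Cardiopulmonary Simulation of Lung Recruitment
    Maneuvers in ARDS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mechanically ventilated patients with acute
    respiratory distress syndrome (ARDS) using a lung divided into 100
    alveolar compartments, each with its own stiffness, threshold opening
    pressure, extrinsic pressure, airway and vascular resistance, and
    opening time-constant. Couples compartmental pressure-volume mechanics
    and time-dependent recruitment/derecruitment hysteresis to per-compartment
    gas exchange (oxyhaemoglobin dissociation, CO2 carriage with Haldane
    correction, hypoxic pulmonary vasoconstriction, shunt and dead space)
    under the Fick principle with fixed cardiac output. Provides builders for
    pressure-controlled ventilation protocols including the maximal
    recruitment strategy (MRS), sustained inflation (SI) and the prolonged
    recruitment maneuver (PRM), a two-stage calibration routine that fits
    virtual patients to static blood-gas records and dynamic PaO2 responses
    to PEEP steps, and experiment drivers for maneuver comparison and PEEP
    titration sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
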