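Package: circleleak
Title: Gas Kinetics of Reservoir-Bag Disconnection in Fresh-Gas-Decoupled
    Circle Breathing Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of room-air entrainment into an
    anesthesia circle breathing system when the reservoir bag of a
    fresh-gas-decoupled workstation is disconnected. Provides a well-mixed
    single-compartment multi-gas circuit model with patient uptake, CO2
    absorption and a lumped entrainment leak; closed-form wash-in/wash-out
    kinetics and theoretical time constants (tau = V_tot/FGF and the
    uptake-corrected Conway form); a six-phase anesthesia protocol runner; a
    gas-monitor emulator (quantization and noise) generating replicate traces;
    the 63%-criterion time-constant estimator; windowed summary statistics and
    Friedman comparisons of inspired gas fractions before, during and after
    disconnection; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
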