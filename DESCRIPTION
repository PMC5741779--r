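Package: catfield
Title: Static Catalytic Fields for Predicting Substituent and Environment
    Effects on Activation Barriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes static catalytic fields, the difference of the
    molecular electrostatic potential between a superimposed transition
    state and substrate state, from atom-centred multipole expansions
    (monopole, dipole, traceless quadrupole). Provides Kabsch rigid-body
    superposition over atom subsets, bond-directed and solvent-accessible
    surface probe placement, additive point-charge estimates of activation
    barrier changes, and linear models relating the catalytic field at
    substitution sites to observed barrier changes. Includes deterministic
    synthetic fixtures (paired substrate/transition-state point-charge
    systems and noisy linear datasets) so the whole pipeline is testable
    without electronic-structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
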