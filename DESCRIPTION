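Package: specbind
Title: Spectroscopic Analysis of Protein-Ligand Binding and Enzyme Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising small-molecule binding to proteins from
    steady-state spectroscopy. Computes enzyme inhibition rates and fits IC50
    dose-response curves, performs inner-filter correction and Stern-Volmer
    quenching analysis with static/dynamic classification, estimates binding
    constants and stoichiometry from double-logarithmic quenching plots,
    derives van't Hoff thermodynamics (enthalpy, entropy, Gibbs energy) with
    sign-rule classification of the dominant binding force, evaluates Forster
    resonance energy transfer (spectral overlap integral, Forster radius,
    donor-acceptor distance) and quantifies conformational evidence from
    UV-vis, synchronous-fluorescence, FT-IR and circular-dichroism data. A
    seeded synthetic-data generator emulates fluorescence titrations,
    dose-response series and Gaussian band spectra so every analysis stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
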