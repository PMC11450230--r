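Package: hak5kin
Title: Steady-State Kinetics of High-Affinity K+/H+ Symport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Closed-form King-Altman solution of a four-state kinetic cycle
    for an electrogenic 1:1 K+/H+ symporter of the plant HAK/KUP/KT family,
    with a symmetric Eyring voltage barrier on the empty-carrier step.
    Provides apparent Michaelis-Menten reductions (K_K, K_H, I_Kmax) and
    voltage scans, thermodynamic uptake limits contrasting channel-mediated
    and proton-coupled potassium uptake, the dose-response fitting layer
    used on two-electrode voltage-clamp recordings (Michaelis-Menten, Hill
    and bell-shaped steady-state fits, percent inactivation), and a seeded
    synthetic-data generator for concentration-step protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
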