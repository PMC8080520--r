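Package: photolaccase
Title: Kinetics of Photoinduced Electron Transfer to a Multicopper Laccase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action modelling of a photoredox system coupling a
    tris-bipyridine ruthenium sensitizer to a fungal laccase, with methyl viologen
    as electron relay and dioxygen as terminal acceptor. Provides a declarative
    reaction-network builder with stiff ODE simulation, optical observable models
    (transient absorbance, emission, Clark-electrode dissolved oxygen), closed-form
    photophysics (driving forces, Stern-Volmer quenching, Forster transfer,
    nonadiabatic Marcus rates and reorganization-energy inference), ready-made
    schemes for laser-flash and continuous-illumination regimes including the
    eight-state T1/trinuclear-cluster redox ladder and aerobic superoxide routing,
    multi-experiment global least-squares fitting, and a seeded synthetic-data
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    lhs,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
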