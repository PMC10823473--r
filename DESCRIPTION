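Package: forcetemper
Title: Infinite-Switch Force Tempering with Replica Exchange on Toy
    Molecular Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Langevin-dynamics sampling of toy molecular systems under an
    infinite-switch simulated-tempering-in-force bias: a single run samples a
    continuous mixture of pulling forces along a collective variable, learns
    the force-weight density on the fly, and reweights recorded observables to
    any force inside the sampled range.  The bias can be combined with
    temperature replica exchange or solute-tempering (REST-style) Hamiltonian
    scaling for systems whose conformational landscape the force bias alone
    cannot cross.  Ships harmonic, double-well and bead-spring-polymer model
    systems, dense-grid quadrature oracles for validation, free-energy-profile
    and force-extension analysis, and a reproducible config-driven runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
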