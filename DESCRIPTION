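Package: fsvqe
Title: Folded-Spectrum Variational Quantum Eigensolver for Molecular Excited States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the folded-spectrum variational quantum eigensolver
    (FS-VQE) for molecular ground and excited electronic states. Builds
    Jordan-Wigner qubit Hamiltonians from packaged spin-orbital integral
    fixtures, performs phase-exact Pauli-string algebra to reduce the
    folded operator (H - omega)^2, partitions Pauli strings into
    simultaneously measurable commuting groups, compiles ordered
    Trotterized unitary coupled cluster circuits, and simulates them
    exactly, with finite shots, or under a tunable depolarizing plus
    thermal-relaxation noise model. Includes SPSA optimization with a shot
    scheduler, potential-energy-surface state tracking, and readout
    (SPAM) plus zero-noise-extrapolation error mitigation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
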