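Package: duotox
Title: Double-Activity Toxicity Compositing and CoMSIA-Style 3D-QSAR for Quinolones
Version: 0.1.0
Authors@R:
    person("Duotox", "Developers", email = "duotox@example.org", role = c("aut", "cre"))
Description: Composites green-algae toxicity (pEC50) and bacterial genotoxicity
    (pLOEC) of quinolone antibiotics into a single double-activity
    characterization value by the comprehensive index method, builds a
    CoMSIA-style similarity-index-field 3D-QSAR on the composite with NIPALS
    partial least squares, leave-one-out q2, external r2pred/SEP, progressive
    response scrambling and StDev*Coeff contour extraction, and implements the
    change-rate arithmetic used to screen candidate derivatives against
    externally computed properties (DFT energies, logKow, half-lives, docking
    scores). Ships the 50-compound quinolone toxicity table as a fixture and a
    seeded synthetic aligned-molecule generator with planted field-activity
    structure for end-to-end recovery testing. Molecular structure perception
    (conformers, charges, donor/acceptor flags, common-scaffold mapping) is
    delegated to a bundled RDKit helper script run through the system Python.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
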