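Package: easiMS
Title: Kinetics-Based General Linear Modeling of Replicate EI Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns per-ion linear abundance models from replicate
    electron-ionization mass spectra of a reference compound and uses them to
    predict fragment-ion abundances in query spectra collected on other
    instruments, for expert-algorithm substance identification. Fragment
    abundances in replicate spectra co-vary strongly because they share the
    same unimolecular dissociation kinetics; a Kassel/RRKM-style branching
    simulator demonstrates that these fragment-fragment relationships are
    approximately linear under modest changes in internal energy or
    observation time, which justifies mixed stepwise ordinary-least-squares
    modeling of each panel ion on the remaining ions. Includes NIST MSP
    import/export, residual diagnostics (moment tests, P-P coordinates,
    residual cross-correlation mapping, centroid baseline), and a synthetic
    spectral-library generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    deSolve,
    e1071,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra-io.R'
    'kinetics.R'
    'ols.R'
    'stepwise.R'
    'coefficient-table.R'
    'diagnostics.R'
    'synthetic.R'
    'cli.R'
    'easiMS-package.R'
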