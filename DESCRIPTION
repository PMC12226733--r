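Package: iGluRphys
Title: Biophysical Analysis of Ligand-Gated Ion Channel Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Electrophysiology and sequence-annotation toolkit for ionotropic
    glutamate receptor (iGluR) biophysics. Estimates reversal potentials from
    current-voltage (I-V) series by polynomial root finding, converts I-V to
    conductance-voltage (G-V) relationships, fits the single permeant blocker
    model of voltage-dependent polyamine (spermine) block to estimate Kd(0 mV)
    and its voltage dependencies, computes bi-ionic relative permeability
    ratios (monovalent/monovalent and divalent/monovalent), fits Hill,
    inhibition, biphasic dose-response and desensitization-recovery kinetics,
    and annotates ligand-binding-domain and pore residues on mature rat GluA2
    numbering to predict glutamate versus glycine/D-serine specificity.
    Includes seeded synthetic-data generators (Goldman-Hodgkin-Katz bi-ionic
    currents, blocker-shaped G-V families, dose-response and recovery tables,
    alignment fixtures) with known ground truth for parameter-recovery
    testing, and a reproducible pipeline driver with tabular/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
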