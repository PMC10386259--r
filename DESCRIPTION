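Package: saltnn
Title: Monovalent Salt Corrections for Nucleic Acid Secondary Structure
    Energy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Debye-Hueckel/Manning counter-ion condensation
    model of monovalent salt effects on RNA and DNA secondary structure
    thermodynamics.  Provides temperature-dependent electrostatic energies
    for loops (freely jointed charged chains) and helices (parallel charged
    rods), salt-correction terms relative to the 1.021 M standard condition,
    a linear multiloop approximation compatible with cubic-time folding
    recursions, salt-corrected nearest-neighbor parameter updates, an
    empirical duplex-initiation correction, dot-bracket structure evaluation,
    two-state melting-temperature prediction and van 't Hoff regression,
    together with the Chen & Znosko empirical comparator fits and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
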