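Package: eperturb
Title: Electrostatic Perturbation Profiling of Holo and Apo Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the electrostatic perturbation induced by ligand or
    cofactor binding by contrasting two structures of the same protein (the
    holo and apo forms). Per-residue electrostatic potentials, evaluated at a
    configurable "reactive atom" per residue type, are turned into pairwise
    electrostatic potential differences (EPDs); each residue's perturbation
    score is the change, between the two forms, of the summed EPDs over its
    holo-defined spatial neighborhood. Residue pairs whose EPD reverses sign
    with a large magnitude change are reported as polarity reversals, and a
    parallel analysis of reactive-atom distances measures spatial deviation.
    Potentials are ingested from an APBS scalar grid in OpenDX format plus a
    PQR file, or computed by a built-in screened-Coulomb fallback from PQR
    charges. Results are written as TSV tables and PyMOL coloring scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
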