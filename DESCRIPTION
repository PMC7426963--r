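Package: fabshift
Title: Free-Versus-Bound Conformational Analysis of Antibody Fab Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares crystal structures of antibody Fab fragments solved in
    the free and antigen-bound states. Provides backbone rigid-body
    superposition (Kabsch), region-resolved RMSD over the variable, linker and
    constant domains, per-residue RMSF profiles under whole-chain or per-domain
    overlap, conserved-anchor hinge angles and distances between the variable
    and constant domains, and a three-way classification (B1/B2/B3) of the
    binding-induced conformational change, including detection of the CH1
    C_Loop1 allosteric signal. A synthetic Fab-couple generator with known
    ground-truth hinge rotations, loop displacements and coordinate noise makes
    every stage of the pipeline testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
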