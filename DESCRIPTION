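Package: polyqconf
Title: Conformational Ensemble Analysis of Polyglutamine Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of conformational ensembles of polyglutamine
    (polyQ) and polyQ-polyproline peptides from backbone dihedral angles and
    coordinates. Provides Ramachandran-region assignment by hard boundaries or
    wrapped k-means clustering, a DSSP-style secondary-structure subset built
    on Kabsch-Sander hydrogen-bond energies, detection of rare extended motifs
    (beta and alpha-sheet-like strands and hairpins, polyproline-II runs, turn
    typing), odds-ratio inter-residue correlation profiles expressed in
    free-energy units with asymptotic standard errors, psi-angle Pearson
    correlation profiles, radius-of-gyration distributions with
    Levenberg-Marquardt Gaussian-mixture decomposition and chain-length
    scaling exponents, and prolyl cis/trans sub-ensemble partitioning. A
    synthetic ensemble generator with controllable region marginals and
    inter-residue correlation structure supports validation of the whole
    pipeline without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
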