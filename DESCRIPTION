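Package: incrdock
Title: Parallelized Incremental Meta-Docking of Flexible Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for docking large flexible ligands to rigid protein
    receptors by incremental fragment growth. Ligands are decomposed into a
    torsion tree of rigid groups connected by rotatable bonds; docking starts
    from a small fragment with a fixed number of actively sampled bonds and
    grows it over successive rounds, docking many fragment copies in parallel
    and pooling their binding modes. The package also implements the two
    baseline protocols this strategy is compared against (a single long engine
    run, and many short independent runs pooled together), a built-in seeded
    stochastic docking engine, an adapter for external Vina-compatible
    binaries, readers and writers for PDB and PDBQT torsion-tree files, a
    redocking evaluation layer (all-atom no-superposition RMSD, top-RMSD
    conformations, 2 Angstrom success calls, replicate statistics and
    benchmark tables), and a generator of synthetic pocket/ligand complexes
    with planted reference poses for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
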