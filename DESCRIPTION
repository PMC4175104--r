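Package: hpfold
Title: Approximate Protein Folding in the HP Model on the 2D Triangular Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Folds hydrophobic-polar (HP) strings on the two-dimensional
    triangular lattice so as to approximately maximise the number of H-H
    contact bonds. The folding engine iteratively fills hexagonal lattice
    regions of decreasing depth, growing a region for each H-run, threading
    it with a serpentine Hamiltonian path, and routing P-runs outside the
    hexagon. Also provides the closed-form point, edge and bond counts for
    regular hexagons, the expected approximation-ratio analysis based on the
    expected number of parts of a random integer partition, an exact
    branch-and-bound oracle for short strings, synthetic HP-string
    generators, plain-text and FASTA-like readers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
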