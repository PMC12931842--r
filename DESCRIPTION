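Package: ripstack
Title: Persistent Homology, Persistent Laplacians, and Persistent
    Stanley-Reisner Invariants from Vietoris-Rips Filtrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three families of multiscale invariants from a single
    Vietoris-Rips filtration of a labelled 3-D point cloud: persistence
    barcodes and (persistent) Betti numbers via boundary-matrix reduction
    over GF(2); combinatorial and persistent Laplacian spectra with harmonic
    multiplicities and smallest-positive-eigenvalue curves; and persistent
    commutative-algebra invariants of the Stanley-Reisner ring, including
    facet persistence barcodes, f- and h-vectors, and graded Betti numbers
    obtained through Hochster's formula.  Ships deterministic geometric
    fixtures (regular octagon, stretched octahedron, regular dodecahedron as
    a C20 fullerene surrogate, parametric helix) and readers for PDB and XYZ
    structure files with backbone-atom selection, so biomolecular point
    clouds (C-alpha or phosphate traces) can be analysed with the same
    machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
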