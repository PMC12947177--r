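Package: loopBP
Title: Protein Loop Closure by Branch-and-Prune Distance Geometry with
    Hydrogen Interval Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates all backbone conformations of a protein loop anchored
    at three fixed C-alpha atoms, formulated as a Discretizable Distance
    Geometry Problem (DDGP) whose vertex order includes the backbone amide and
    alpha hydrogens.  Short-range hydrogen-hydrogen distances, of the kind
    measurable by NMR, enter the graph as interval restraints: one drives the
    interval discretization step of the Branch-and-Prune (BP) search and the
    rest prune candidate positions.  Includes exact sphere-intersection
    kernels, reconstruction of missing backbone hydrogens from ideal geometry,
    a synthetic loop generator with known ground truth, anchored-frame RMSD
    scoring, comparison of the hydrogen-rich and hydrogen-reduced orders, and
    PDB/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
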