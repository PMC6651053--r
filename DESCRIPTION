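Package: Pattern3D
Title: Discovery of Conserved Three-Dimensional Amino Acid Patterns in
    Protein Structures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive, ligand-agnostic discovery of conserved
    three-dimensional amino acid arrangements (3D-patterns) shared by an
    arbitrary set of protein structures. Each structure is covered by a
    grid of virtual reference coordinates; every grid point (optionally
    expanded into displaced elliptical search zones) that gathers at
    least four residues within a search radius defines a candidate site.
    Sites are canonicalized into composition signatures, clustered by
    minimal root-mean-square deviation under optimal rigid-body
    superposition with residue-correspondence search, and unified into a
    pattern/cluster/site graph with protein-coverage and
    cluster-coverage statistics, regular-expression sub-pattern queries,
    sequence views of structural alignments and superposed-coordinate
    export. Includes a synthetic-structure generator that plants
    rigid-body-transformed motifs among decoy residues for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
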