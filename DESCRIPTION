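Package: protofibril
Title: Molecular Dynamics of Early Cellulose Protofibril Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale all-atom molecular dynamics of the first stages of
    cellulose protofibril assembly. Builds extended beta-1,4-glucan chains
    with explicit hydrogens, anchors six of them on a circle emulating one
    globule of a rosette cellulose synthesis complex, and propagates them
    under NVT (Nose-Hoover) dynamics with a Dreiding-form force field
    (harmonic bonds and valence angles, three-cosine dihedrals, 12-6
    nonbonded terms with deepened hydrogen-bond wells, no electrostatics).
    Includes spring-guided tower preassembly, free relaxation, assembly on
    a frozen phospholipid-headgroup surface, monomer-by-monomer extrusion
    growth, and bending under a descending impenetrable wall, together
    with the analyses that yield the study observables: hydrogen-bond
    inventories, chain pairing partitions, basal bend angles, fibril
    cross-sections, and contact/stability monomer thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Rcpp,
    bio3d,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
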