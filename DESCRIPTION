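Package: tomotwist
Title: Twist-Vector Neighborhood Descriptors for Oriented Particles from
    Cryo-Electron Tomography
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rotationally invariant spatial analysis and curation of oriented
    particle lists from cryo-electron tomography and subtomogram averaging.
    Relative poses between neighboring particles are encoded as SE(3) twist
    vectors computed in each query particle's canonical frame, yielding
    descriptors that are invariant under global rigid motions of the scene.
    On top of the twist descriptor the package provides geometric supports
    (spheres, cylinders, ellipsoids, cones, tori, binary masks) and record
    filters, per-query features (occupancy, distance statistics, shell
    decompositions, lattice link statistics, rotation-axis histograms,
    cone-occupancy footprints), a symmetry-ambiguity-free angular score for
    cyclic and platonic-solid symmetric particles, proximity clustering for
    object affiliation and geometric cleaning, and analysis pipelines for
    lattice-defect (pentamer) detection, nucleosome stack and dinucleosome
    pattern mining, and footprint/axis pattern detection. Readers and writers
    for Relion STAR, TOM/AV3 motive lists, Dynamo tables and a plain CSV
    dialect are included, together with seeded synthetic-data generators
    (planar lattices, ring assemblies, chromatin-like mixtures) and a noise
    corruption model so that every pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
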