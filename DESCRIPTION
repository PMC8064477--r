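Package: chemoarray
Title: Lattice Models and Baseplate Connectivity Analysis for Bacterial
    Chemosensory Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds coarse-grained molecular models of bacterial
    chemosensory arrays by tiling core-signalling units (two receptor
    trimers-of-dimers, a CheA dimer and two CheW monomers) into p2- or
    p6-symmetric lattices on planar or spherical membranes.  Analyses the
    CheA/CheW baseplate as a docking-site contact graph: classifies the
    three pseudosymmetric ring interfaces, enumerates six-membered
    baseplate rings, computes per-unit interface censuses and
    receptor-to-kinase connectivity.  Classifies rendered or simulated
    density by rotational self-similarity, estimates lattice periodicity
    by autocorrelation, fits spheres to membrane point clouds, projects
    volume density onto curved surfaces (membranograms), and generates
    synthetic tomogram-like volumes with noise and a missing wedge for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
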