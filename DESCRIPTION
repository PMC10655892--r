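Package: condensac
Title: Brownian-Dynamics Simulation of Mitotic Chromosome Compaction by
    Condensin Looping and Bridging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A coarse-grained bead-spring polymer model of mitotic chromosome
    folding. A prophase chromosome is represented as a bottlebrush polymer of
    consecutive chromatin loops held by static loop-closure springs ("looping
    condensins"); diffusing multivalent binder particles ("bridging
    condensins") bind weakly to chromatin and strongly to loop anchors, and
    their bridging-induced attraction compacts the bottlebrush into a stiff
    self-assembled cylinder. The package provides an underdamped Langevin
    integrator with neighbour-listed force evaluation (Rcpp), topology
    builders for uniform and Poisson-distributed loops, sister chromatids,
    condensin knockouts and fragile-site perturbations, experiment protocols
    (compaction, constant-force extension-retraction cycles, scenario runs),
    and the full analysis suite: gyration-tensor shape descriptors,
    tangent-tangent correlations and persistence length, contact-probability
    scaling P(s), bridge clustering and valence, chromosome extension and
    width, simulated FISH probe distances, and bottlebrush bristle-repulsion
    estimates. Trajectories are read and written as extended XYZ and LAMMPS
    dump text; topologies export to LAMMPS data files for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
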