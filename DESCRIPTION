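Package: fullermem
Title: Fullerene Aggregation and Lipid-Membrane Perturbation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the self-assembly of C60 fullerene
    nanoparticles and their perturbation of phospholipid bilayers. Provides a
    rigid 60-site truncated-icosahedron C60 model with atomistic Lennard-Jones
    pair energetics, an orientation-averaged effective pair potential with
    basin-hopping global minimisation of small (C60)N clusters (N = 3-6),
    distance-cutoff cluster detection with stacking-motif classification, an
    overdamped Langevin generator of synthetic aggregation and membrane
    partitioning trajectories with an implicit membrane slab, a parametric
    pseudo-bilayer builder, and membrane structural metrics: insertion depth,
    number-density profiles along the bilayer normal, the lipid orientational
    order parameter from minimal-moment-of-inertia molecular axes, and
    grid-based bilayer thickness and area per lipid. Reads and writes GRO
    single frames and multi-frame XYZ trajectories in nanometre units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
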