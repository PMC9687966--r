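Package: hydrochan
Title: Channel Hydration, Water Mobility and Hydrogen-Bond Network Analysis
    of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of water behaviour inside protein channels from
    molecular dynamics trajectories. Defines the channel region as the
    per-frame convex polyhedron spanned by user-chosen corner residues,
    envelops it in a discretised cylinder (slices, radial rings, angular
    segments), and computes hydration levels and occupancy profiles,
    slice-resolved water diffusion coefficients from mean squared
    displacements, geometric hydrogen-bond statistics with continuous
    any-water survival lifetimes from bi-exponential fits of the bond
    autocorrelation, water-mediated residue connectivity networks, and
    side-chain conformational statistics (chi dihedrals, distance
    conventions, up/down classification). Includes a synthetic-trajectory
    generator with known ground truth (confined Brownian waters, two-state
    Markov hydrogen-bond processes) for end-to-end validation, plus PDB/DCD
    input-output and a replica-averaging pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
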