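Package: curvsort
Title: Curvature Sorting and Trajectory Analysis for Rotary Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for rotation-driven curvature sorting of
    ATP synthases in lipid bilayers. Provides readers and writers for
    quasi-planar coarse-grained bilayer trajectories (GRO, multi-frame
    PDB) with a JSON bead-group sidecar; a synthetic trajectory
    generator with known ground truth (undulation modes, local bilayer
    thinning, laterally diffusing proteins in a short-range attractive
    pair potential, stepwise rotor rotation, slope-coupled tilts);
    membrane profile and circumradius curvature analysis; protein
    clustering frequencies, close-contact lifetimes and Boltzmann
    inversion of pair-distance distributions into effective interaction
    potentials; bilayer thickness and area-per-acyl-chain profiles with
    curvature correction; tilt and rotation kinematics;
    autocorrelation-aware bootstrap and block-subaverage tests; and the
    tether-pulling sorting-ratio, tube-radius and spontaneous-curvature
    wedge arithmetic used to quantify curvature sorting in tube-pulling
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
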