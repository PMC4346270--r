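Package: memlip
Title: Lipid-Protein Interaction Analysis for Membrane Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for membrane-protein simulations with a focus
    on anionic-lipid (cardiolipin) binding sites: contact occupancy with
    per-species distance cutoffs, binding-site residence times and
    single-lipid exchange counting, per-leaflet lateral density maps and
    annular enrichment ratios, lateral diffusion from mean square
    displacement, Kabsch superposition (RMSD, RMSF, domain-fit probe
    distances), and sphere-fitting pore-radius profiles along a transport
    axis. Includes a seeded Brownian/Metropolis synthetic-bilayer generator
    with discrete sticky binding sites and known ground truth, so every
    estimator can be validated against closed-form expectations, plus
    system-composition helpers (lipid-exchange planning and neutralizing-ion
    arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
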