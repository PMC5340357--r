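Package: radiolyze
Title: Collision-Event Analysis and Species Census for Ion Tracks in Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    hyperthermal projectiles traversing liquid water in the adiabatic
    (nuclear stopping) regime. Reads and writes an extended-XYZ trajectory
    dialect, computes projectile energy-loss profiles and final kinetic
    energies, segments profiles into discrete collision events and
    continuous vibrational loss, performs a coordination-number species
    census (water, hydroxyl, hydronium, isolated H and O, molecular
    hydrogen, peroxide) under periodic boundary conditions, assigns charge
    labels to fragments from per-atom electron populations, and aggregates
    trajectory ensembles into nuclear stopping powers, final-energy
    histograms and fragment production spacings. A synthetic event-kinematic
    track generator with ground-truth event logs makes every analysis stage
    testable without electronic-structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
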