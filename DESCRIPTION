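Package: probemap
Title: Probe-Confined Dynamic Mapping of Receptor Binding-Site Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for probe-confined dynamic mapping of
    receptor surfaces. Small-molecule probes are confined near a chosen
    receptor face by a cylindrical flat-bottom harmonic wall and sampled
    with rigid-body Langevin dynamics under a Coulomb plus Lennard-Jones
    force field. Trajectories are analysed for pocket occupancy, voxelised
    probe density grids, per-residue electrostatic and van der Waals
    interaction-energy hotspots, hydrogen bonds, contact frequencies,
    RMSF/RMSD, solvent-accessible surface area and grid-based pocket
    volume. Includes four-parameter logistic concentration-response
    fitting with the extra sum-of-squares F test, deterministic synthetic
    fixtures (toy receptors with planted attractive pockets, planted
    hotspot trajectories, simulated dose-response data), and readers and
    writers for PDB, XYZ and DCD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
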