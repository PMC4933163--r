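Package: cetransit
Title: Tunnel Geometry, Transfer Kinetics, and Biophysics of Cholesteryl
    Ester Transit Through CETP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cholesteryl ester (CE) transit through the
    hydrophobic tunnel of cholesteryl ester transfer protein (CETP).
    Provides probe-sphere diameter and greedy pathway profiling of protein
    tunnels, SASA-weighted Kyte-Doolittle hydrophobicity profiles along a
    ligand trajectory, power-law fitting of steered transfer times against
    driving force, a Young-Laplace model of lipoprotein internal pressure
    that converts particle surface tension and size into a physiological
    driving force and predicted per-molecule transfer times, conversions of
    radiolabel transfer rates to per-molecule kinetics, and standard
    trajectory metrics (Kabsch RMSD, RMSF, radius of gyration, grid
    molecular volume, RDF first peak). A synthetic-data module generates
    barrel structures with known tunnels, ligand trajectories, replicated
    force-time tables, and overdamped Langevin first-passage times so the
    full pipeline is testable without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
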