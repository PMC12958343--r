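Package: twofab
Title: Interface Hotspots and Aggregation-Kinetics Models from Two-Fab Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for molecular-dynamics trajectories of two
    antibody Fab fragments diffusing in a periodic box. Computes residue-level
    inter-body contact-frequency maps under a 6 Angstrom cutoff, calls
    protein-protein interaction hotspots, clusters contacting frames by PCA and
    merges spatially adjacent interface regions into hotspot groups, segments
    contact events and transitions, derives a 24-descriptor molecular feature
    table (Shrake-Rupley SASA and region-wise delta-SASA, RMSD, RMSF, radius of
    gyration, hydrogen bonds, salt bridges, native contacts, net charge), and
    fits aggregation-kinetics regression models ln(v) ~ features via exhaustive
    subset search over SHAP-ranked descriptors with cross-validated grid search
    (multiple linear regression, partial least squares, epsilon-support-vector
    regression, decision trees, random forests). Includes seeded synthetic
    two-body trajectory and feature-table generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    quadprog,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
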