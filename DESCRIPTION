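Package: bamdyn
Title: Conformational Dynamics Analytics for the Beta-Barrel Assembly Machinery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory- and structure-derived metrics for the conformational
    dynamics of the beta-barrel assembly machinery (BAM) and related outer
    membrane protein complexes: the in-plane rotation angle of the periplasmic
    lipoprotein ring, backbone hydrogen-bond time series at the BamA lateral
    seam with open/tenuous/closed state classification, in-plane tracking of
    the POTRA5 domain with explored-area estimates, Kabsch superposition and
    RMSD between conformational states, disulfide-crosslink distance screening
    for conformation-locking cysteine pairs, and a seeded Monte-Carlo
    simulation (with an exact analytic oracle) of how randomly positioned
    nanodisc scaffold density averages out during single-particle alignment.
    A synthetic-structure generator provides ground-truth complexes and
    trajectories so every metric is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
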