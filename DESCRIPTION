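Package: radcurve
Title: Sliding Semi-Landmark Morphometrics of Radial Head Outlines and
    Radius Curvature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers forearm posture and active pronation ability from
    radius morphology. Implements an outline-based geometric morphometric
    pipeline for 2D radial-head outlines (TPS landmark input, arc-length
    resampling to one fixed landmark plus 20 semi-landmarks, partial
    Procrustes generalized superimposition, minimum-bending-energy sliding
    of semi-landmarks, thin-plate-spline principal/partial/relative warps
    with broken-stick variance assessment), a three-point angle-of-curvature
    metric of the radial shaft, permutation-based group comparison via
    Goodall's F on partial Procrustes distances with Bonferroni control,
    Kruskal-Wallis multiple comparisons for the angle data, Blomberg's K
    phylogenetic-signal tests on warp scores, and a synthetic-data
    generator (outlines, angles, trees with Brownian traits) so the whole
    pipeline is testable without external specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
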