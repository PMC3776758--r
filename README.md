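# radcurve

Quantitative inference of forearm posture and active pronation ability
from radius morphology.

In sprawling tetrapods (crocodylians, most squamates, monotremes) the
radius is straight and lies parallel to the ulna; the manus cannot be
actively pronated. In parasagittal mammals the radial head is rounded so
it can rotate against the ulna, and the shaft is curved so the radius can
cross the ulna and keep the manus directed cranially. `radcurve`
implements the two quantitative signals of this dichotomy and the full
statistical chain around them, so postural hypotheses for extinct taxa
(e.g. quadrupedal dinosaur clades) can be tested against extant groups of
known posture:

* **Radial-head outline shape** — sliding semi-landmark geometric
  morphometrics of closed 21-point outlines (one fixed landmark at the
  ulnar articular surface + 20 semi-landmarks): TPS file I/O, arc-length
  resampling, partial Procrustes generalized superimposition (centroid
  size fixed at 1), minimum-bending-energy sliding, thin-plate-spline
  principal/partial/relative warps with broken-stick variance
  assessment.
* **Angle of curvature** — the three-point angle between the radial-head
  plane and the shaft's long axis; 90° reads as a straight radius unable
  to cross the ulna.
* **Inference** — Goodall's *F* on partial Procrustes distances,
  `F = [d²(x̄₁, x̄₂)/(1/n₁ + 1/n₂)] / [(Σᵢd²(xᵢ, x̄)) / (n₁ + n₂ − 2)]`,
  tested by label permutation with the superimposition held fixed;
  pairwise batteries at Bonferroni-corrected levels (`0.05 / choose(g, 2)`);
  tie-corrected Kruskal–Wallis with mean-rank multiple comparisons for
  the angle data; Blomberg's *K* phylogenetic-signal tests on warp
  scores.
* **Synthetic study generator** — groups of outlines whose mean shapes
  differ by a controlled partial Procrustes distance under isotropic
  landmark noise, per-group angle distributions, and Brownian-motion
  traits on simulated ultrametric trees, so the entire pipeline runs and
  is testable with no external data.

See the methods vignette (`vignettes/radial-head-morphometrics.Rmd`) for
the models, conventions and design decisions.

## Worked example

A complete synthetic study — two postural groups, outline shapes offset
by a partial Procrustes distance of 0.1 under coordinate noise 0.02,
straight (90°) vs curved (75°) angle groups — analysed end to end:

```r
library(radcurve)

dir <- tempfile(); dir.create(dir)
gen <- generate_outlines(n_per_group = 15, delta = 0.1, noise_sd = 0.02,
                         seed = 3,
                         tps_path = file.path(dir, "outlines.tps"),
                         csv_path = file.path(dir, "groups.csv"))
ang <- generate_angles(n_per_group = 15, seed = 3,
                       csv_path = file.path(dir, "angles.csv"))

cfg <- run_config(file.path(dir, "outlines.tps"),
                  file.path(dir, "groups.csv"), scheme = "group",
                  angle_csv = file.path(dir, "angles.csv"),
                  out_dir = file.path(dir, "out"),
                  n_permutations = 1999, seed = 42)
res <- run_full_analysis(cfg)

print(res$gpa)
#> Partial Procrustes superimposition: 30 specimens, 21 landmarks
#>   iterations: 11 (converged) with semi-landmark sliding
#>   Procrustes distances to consensus: mean 0.02982 , max 0.04658

print(res$rw)
#> Relative warps: 30 specimens, 38 axes
#>   variance proportions (first 5): 55.479%  9.555%  6.747%  5.040%  3.676 %

print(res$pairwise)
#> Pairwise Goodall's F battery: 2 groups, 1 tested pairs
#>   Bonferroni-corrected alpha: 0.05
#>   significant pairs: parasagittal vs sprawled

print(res$kw)
#> Kruskal-Wallis: H = 21.77, df = 1, p = 3.067e-06
#>   Bonferroni-corrected pairwise alpha: 0.05
```

Reading the output: the superimposition converged with semi-landmark
sliding; the first relative warp carries 55.5% of shape variance (the
injected group offset dominates it); the shape battery recovers the
group difference (Goodall's *F* = 125.84, permutation *p* = 5e-04, the
floor for 1999 permutations) and the angle test separates the straight
from the curved group (*H* = 21.77). The output directory contains the
aligned shapes (`aligned.tps`, `aligned_long.csv`), relative warp scores
and the variance table with broken-stick expectations, the pairwise
`F`/`p` matrices plus a publication-style lower-triangle table, the
angle test results, an ordination plot with group convex hulls, and a
JSON manifest (seed, permutation count, config hash) that makes the run
byte-for-byte reproducible.

A shell entry point with `simulate` and `run` subcommands is installed
at `inst/scripts/radcurve.R`.

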