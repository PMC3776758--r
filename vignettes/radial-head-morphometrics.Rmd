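---
title: "Inferring forearm posture from radial morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring forearm posture from radial morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcurve)
```

## The scientific problem

In sprawling tetrapods (crocodylians, most squamates, monotremes) the
radius lies parallel and medial to the ulna, its shaft is straight, and
the manus cannot be actively pronated. In parasagittal mammals the radius
crosses the ulna: the radial head is rounded so it can rotate against the
ulna and distal humerus, and the shaft is curved so the distal radius
reaches the medial side. Two measurable features of the radius therefore
carry a postural signal:

* the **outline shape of the radial head** in proximal view, and
* the **angle of curvature** relating the plane of the radial head to the
  long axis of the shaft (90° reads as a straight shaft; departures from
  90° as a shaft curved enough to cross the ulna).

`radcurve` implements the full quantitative chain that turns these two
measurements into statistical statements about posture and active
pronation ability, calibrated on extant groups of known posture and
applicable to extinct taxa such as quadrupedal dinosaur clades. A
synthetic-data generator with the same statistical structure makes every
stage testable without specimen photographs or museum access.

## Outline data and its conventions

Radial-head outlines enter as TPS landmark records: one *fixed landmark*
at the middle of the ulnar articular surface (the only point with a
point-to-point anatomical identity across taxa) followed by 20
*semi-landmarks* traced clockwise around the head. `read_tps()` honours
`LM=`, `ID=`, `IMAGE=` and `SCALE=` keys and treats coordinates as y-up
Cartesian, the digitizer convention, rather than image rows. Unknown keys
are ignored with a warning rather than an error, because TPS dialects
vary across digitizing tools.

Three normalization rules are enforced at load time so that downstream
code never sees inconsistent data:

* **21 points** — `resample_outline()` re-spaces a dense traced curve to
  equal arc-length steps, keeping point 1 exactly at the fixed landmark.
  Equal spacing by cumulative arc length removes the arbitrary density of
  hand tracing; with at least a few hundred traced vertices the residual
  spacing error is far below digitizing noise.
* **Clockwise order** — enforced as negative signed area;
  counter-clockwise inputs are reversed with a warning.
* **Left-equivalent forms** — right radii are mirrored (`x -> -x`) by
  `standardize_sides()` and flagged, so reflections never enter the
  superimposition, which is rotation-only by design.

## Superimposition model

`gpa()` performs *partial* Procrustes generalized superimposition:
translation, rotation and isometric size are removed and every
configuration — including the consensus — is held at centroid size
exactly 1. Scale is not re-optimized during rotation (the "partial"
convention, generally preferred for outline data). Rotations are solved
in closed form by representing configurations as complex vectors, which
also gives the partial Procrustes distance directly.

The iteration alternates aligning all specimens to the current consensus
with recomputing the consensus as the re-normalized coordinate mean, and
stops when the root-mean-square change in the consensus drops below
`tol = 1e-8` (default; `max_iter = 100`). The unquantified "stops
changing significantly" convergence idea is made concrete by these two
numbers; on realistic data convergence takes a handful of iterations.
Two non-obvious numerical choices:

* each sweep re-rotates the updated consensus onto the previous one, and
  the converged solution is finally rotated so the consensus' fixed
  landmark lies on the positive x-axis. Without the first step the
  solution can drift indefinitely along the orbit of equivalent
  rotations (the fixed-point family is rotation-invariant) and the RMS
  criterion never triggers; the second makes output *invariant*, not
  merely equivariant, under any common similarity transform of the raw
  data, which is what reproducibility tests demand.
* Procrustes distances are computed from the rotated difference vector
  rather than the algebraically equal `sqrt(2 - 2|s|)`, which loses half
  the significant digits to cancellation for nearly identical shapes.

## Sliding semi-landmarks

Semi-landmarks have no individual anatomical identity, so variation
*along* the outline is noise. With `slide = TRUE`, `gpa()` interleaves
minimum-bending-energy sliding: each semi-landmark may move only along
its tangent direction (cyclic central difference of its outline
neighbours, evaluated on the specimen's own current configuration), and
the vector of signed sliding amounts minimizes the thin-plate-spline
bending energy of the deformation from the consensus to the slid
configuration. This is a quadratic form in the sliding amounts, so the
minimum is a single linear solve per specimen; a ridge term (1e-10) is
added only if the system is numerically singular, with a warning. The
fixed landmark never slides. The schedule is three outer cycles of
(slide, re-superimpose) followed by a final superimposition — the
criterion defines the target, the schedule is a pragmatic choice that in
practice converges after the first cycle. Slid configurations are
re-centred and re-scaled, since sliding perturbs the centroid. Each pass
asserts that total bending energy did not increase.

## Warp decomposition and ordination

`bending_energy_matrix()` uses the standard 2D thin-plate-spline
construction with kernel `U(r) = r^2 log(r^2)` (the alternative
`r^2 log r` halves eigenvalues but leaves all warp directions, scores and
ordinations unchanged). Its eigenvectors with positive eigenvalue — of
which a non-degenerate k-point consensus has exactly k − 3 — are the
principal warps; the matrix annihilates the affine subspace by
construction.

`partial_warp_scores()` projects Procrustes residuals onto the principal
warps separately in x and y (2(k − 3) columns; 36 for the 21-point
scheme), appending two uniform-component columns by default. The uniform
basis is built as the orthonormal complement of the similarity
directions plus the non-uniform warp subspace, which is unique up to
rotation within its two dimensions — any choice gives identical
ordinations. Warps are equally weighted (the α = 0 convention), so a PCA
of the score matrix is exactly a PCA of the residuals restricted to the
corresponding subspace; the test suite verifies this equivalence
directly, mirroring the cross-check that an RWA and a plain PCA of warp
scores coincide.

`relative_warps()` eigen-decomposes the covariance of the centred score
matrix. Axis signs are fixed by making each loading's largest-magnitude
entry positive, so output is reproducible across eigen-solvers.
`broken_stick()` supplies the conventional null spectrum
`E(p_k) = (1/S) * sum_{i=k..S} 1/i` for judging which axes summarize
more variance than chance, and `shape_along_axis()` reconstructs
outline shapes at chosen scores (score 0 returns the consensus exactly;
reconstruction is linear in the score).

## Group inference

**Goodall's F with permutation.** Because 20 of the 21 points are
semi-landmarks, coordinate-wise parametric tests are inappropriate; group
differences are tested on partial Procrustes distances.
`goodall_f()` computes the classic between/within ratio of Procrustes
sums of squares after joint superimposition of the two groups, and
`permutation_test()` refers it to a label-shuffling null with the
superimposition held fixed (only labels move). The p-value estimator
`(1 + b) / (1 + B)` includes the observed statistic, so p is never 0 and
never below `1/(B + 1)`; when the number of distinct label splits is at
most 10,000 the test silently switches to exhaustive enumeration and
reports the exact tail proportion. The default `B = 1999` balances
p-value resolution against the Bonferroni thresholds in use (0.0018
needs resolution well below itself).

**The pairwise battery.** `pairwise_shape_tests()` runs every unordered
pair, each pair re-superimposed in isolation — matching the behaviour of
the two-group desktop tools this workflow historically used — with
`global = TRUE` available for sensitivity analysis against a single
shared superimposition. Pairwise superimpositions default to no sliding;
sliding is available via `slide = TRUE` when the analysis protocol slides
before testing. The familywise level is Bonferroni-shared over *all*
declared pairs (`0.05 / choose(g, 2)` — 0.002, 0.0018 and 0.0011 for 7,
8 and 10 groups), including pairs later skipped for singleton groups, so
the threshold does not silently loosen when a group is too small to
test.

**Angle of curvature.** `angle_of_curvature()` is the interior angle at
the proximal lateral radial-head point between rays to the distal shaft
and across the head to the medial surface. The two source descriptions
of the digitization differ slightly in wording (lateral vs medial distal
end); what is invariant is that the vertex sits at the radial-head
corner shared by both rays, and that is what the function fixes. The
angle is mirror-invariant, so left/right standardization does not affect
it. Since angle distributions are non-normal across such disparate taxa,
`kruskal_wallis_mc()` applies the tie-corrected Kruskal–Wallis H
(delegated to `stats::kruskal.test`) with the classic mean-rank
multiple-comparison criterion at a Bonferroni-shared level. The
significance *decision* is always the mean-rank criterion; the reported
per-pair p is the exact rank-sum enumeration when the pair is small and
tie-free, the normal approximation otherwise. `classify_curvature()`
labels angles straight/curved around 90° with an explicit, reported
tolerance (default 0: classification is offered as a utility and never
feeds the statistics).

**Phylogenetic signal.** `blomberg_k()` implements the K statistic as
the observed-to-Brownian-expected ratio of MSE0/MSE under the tree's tip
covariance, with a seeded tip-shuffling permutation p (999 by default).
The unit tests cross-check the statistic against `phytools::phylosig`.
For matrix-valued traits (relative warp scores) `multivariate_k()`
reports per-axis K plus a variance-weighted summary with a joint
permutation p. This per-axis reading is one plausible treatment of a
score matrix; a single "matrix K" is deliberately not defined because no
standard construction exists, and published K values far above 1 for
score matrices are not reproducible from any documented formula.

## The synthetic study

`generate_outlines()` builds groups of 21-point outlines around two
analytic archetypes: a rounded/elongate head (the parasagittal,
actively pronating morphology) and a reniform head compressed toward the
articular surface (the sprawling morphology). Group means differ from
the archetype by a smooth localized bulge opposite the fixed landmark —
qualitatively mimicking elongation away from the articular surface —
scaled by root-finding so the partial Procrustes distance between
archetype and group mean equals the requested `delta` essentially
exactly. Specimens add isotropic Gaussian coordinate noise (`noise_sd`),
the simplest defensible model of digitization error, applied in the raw
frame before any superimposition.

Defaults are the study conditions used throughout the tests and the
acceptance script: `delta = 0.08`, `noise_sd = 0.02`, 20 specimens per
group; angle groups at 90° (straight, the anchor of the metric) and 75°
(curved) with 5° spread, truncated to (0, 180); trees are pure-birth and
ultrametric with Brownian traits (`ape::rphylo`, `ape::rTraitCont`).
What the generator deliberately does *not* emulate: the covariance
structure of real radial outlines, allometry, digitizer autocorrelation
along the outline, and phylogenetic structure in the shape data itself.
Passing tests therefore demonstrate correctness of the machinery and
calibration of the tests under a known, idealized model — not that any
particular biological dataset satisfies that model.

## Problem sizes and calibration checks

The simulation-based checks use sizes chosen to make their Monte Carlo
error small relative to the bands they assert: 500 null studies for the
type-I calibration of the two-group permutation test (band 0.03–0.07 at
α = 0.05), 200 null studies for the familywise error of the three-group
battery (asserted ≤ 0.05 plus two binomial standard errors), 200
replicates of 64-tip trees for the Brownian calibration of K (mean in
[0.85, 1.15] under Brownian motion, well below 0.6 under white noise),
and 100 paired replicates for the K(BM) > K(white) comparison. The
permutation count inside simulated tests is reduced (99–199) since only
rejection at the corrected level, not the p-value itself, is consumed.

## Degenerate inputs and edge policies

* All-coincident landmarks: centroid size 0 is flagged; such
  configurations cannot be scaled and are rejected by `gpa()`.
* Duplicate landmarks in a consensus make the TPS system singular;
  `bending_energy_matrix()` names the offending pair.
* Zero within-group scatter with distinct means returns `F = Inf` with a
  warning (judged against the ~1e-15 numerical floor of unit inner
  products, not exact zero).
* A constant trait has no definable K (zero variance) and errors; a
  constant angle table yields H = 0 and no significant pairs.
* Singleton groups in the battery are skipped pair-by-pair with
  warnings; the Bonferroni denominator still counts them.
* Exhaustive permutation replaces random shuffling below 10,000 splits,
  so tiny groups (the n = 2 and n = 3 cases common with rare taxa) get
  exact p-values automatically.

## Known limitations

* 2D outlines only; no 3D landmarks, no torsion of the shaft.
* Rotation-only alignment assumes sides were standardized at load; data
  mixing reflections without a `side` column will superimpose poorly.
* The sliding criterion is minimum bending energy only (the Procrustes
  distance sliding criterion is not offered).
* The angle classification threshold ("how far from 90° is curved?") is
  a user decision; the package reports, it does not adjudicate.
* Reproducing specimen-level published values requires the original
  deposited landmark and grouping files; the synthetic generator shares
  their structure, not their numbers.
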