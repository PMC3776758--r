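# Synthetic data with the statistical structure the analysis assumes:
# groups of closed 21-point radial-head outlines whose mean shapes differ
# by a controlled partial Procrustes distance under isotropic landmark
# noise; per-group angle-of-curvature distributions; Brownian-motion
# traits on simulated ultrametric trees. Every generator is a pure
# function of its parameters and seed.

#' Archetype radial-head outlines
#'
#' Hand-built smooth closed 21-point outlines (one fixed landmark at the
#' middle of the articular surface plus 20 semi-landmarks, clockwise):
#' `"rounded"` is an elongate/rounded head like that of parasagittal
#' active pronators; `"reniform"` a kidney-shaped head compressed toward
#' the articular surface like that of sprawling limited pronators. Both
#' are analytic curves, not digitized from any specimen.
#'
#' @param name `"rounded"` or `"reniform"`.
#' @param k total points (default 21).
#' @return k x 2 landmark configuration (clockwise, fixed landmark first).
#' @export
outline_archetype <- function(name = c("rounded", "reniform"), k = 21) {
  name <- match.arg(name)
  m <- 720
  th <- 2 * pi * (seq_len(m) - 1) / m
  r <- switch(name,
    rounded  = 1 + 0.25 * cos(th) + 0.10 * sin(2 * th),
    reniform = 1 - 0.30 * cos(2 * th) + 0.12 * cos(th))
  # theta measured from the fixed landmark (articular-surface midpoint);
  # negative angular direction gives a clockwise trace in y-up coordinates
  pts <- cbind(r * cos(-th), r * sin(-th))
  suppressWarnings(resample_outline(pts, n_semilandmarks = k - 1,
                                    start = 1))
}

# smooth deformation field: outward radial bulge centred opposite the
# fixed landmark (mimicking elongation away from the articular surface)
.offset_field <- function(archetype, center_frac = 0.5, width = 0.15) {
  k <- nrow(archetype)
  ctr <- colMeans(archetype)
  rel <- sweep(archetype, 2, ctr)
  rn <- sqrt(rowSums(rel^2))
  u <- rel / rn
  frac <- (seq_len(k) - 1) / k
  circ <- pmin(abs(frac - center_frac), 1 - abs(frac - center_frac))
  w <- exp(-circ^2 / (2 * width^2))
  u * w
}

# scale factor s so that procrustes_distance(archetype, archetype + s*field)
# equals delta (solved numerically; exact within uniroot tolerance)
.calibrate_offset <- function(archetype, field, delta) {
  if (delta == 0) return(0)
  f <- function(s) procrustes_distance(archetype,
                                       archetype + s * field) - delta
  upper <- 0.05
  while (f(upper) < 0 && upper < 100) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Generate synthetic outline groups
#'
#' Each group's mean shape is the archetype deformed along a fixed smooth
#' field (a localized outward bulge opposite the fixed landmark; successive
#' groups bulge at shifted outline positions) scaled so the partial
#' Procrustes distance between the archetype and the group mean equals
#' `delta`; specimens add isotropic Gaussian noise of standard deviation
#' `noise_sd` to every coordinate. Group 1 is the undeformed archetype.
#' Deterministic under `seed`.
#'
#' @param n_per_group specimens per group (default 20).
#' @param delta target partial Procrustes distance between group mean and
#'   archetype (default 0.08, shape units).
#' @param noise_sd isotropic per-coordinate noise (default 0.02, applied
#'   in the raw frame before any superimposition).
#' @param groups group labels (default `c("sprawled", "parasagittal")`).
#' @param archetype archetype name passed to [outline_archetype()].
#' @param seed integer seed.
#' @param tps_path,csv_path optional output paths: the TPS file of all
#'   specimens and the CSV group table.
#' @return list with `records` (`tps_records`), `groups` (data.frame with
#'   `specimen_id`, `taxon`, `side`, `group`), `group_means` (list of k x 2
#'   matrices), `delta_realized` (per-group achieved archetype-to-mean
#'   distance).
#' @export
generate_outlines <- function(n_per_group = 20, delta = 0.08,
                              noise_sd = 0.02,
                              groups = c("sprawled", "parasagittal"),
                              archetype = "rounded", seed = 1,
                              tps_path = NULL, csv_path = NULL) {
  if (delta < 0 || noise_sd < 0) stop("delta and noise_sd must be >= 0")
  if (delta > 0.3 || noise_sd > 0.08)
    warning("large delta or noise_sd may produce self-intersecting outlines")
  base <- outline_archetype(archetype)
  G <- length(groups)
  means <- vector("list", G)
  means[[1]] <- base
  delta_real <- numeric(G)
  if (G > 1) for (g in 2:G) {
    field <- .offset_field(base, center_frac = 0.5 + 0.25 * (g - 2) / G)
    s <- .calibrate_offset(base, field, delta)
    means[[g]] <- base + s * field
    delta_real[g] <- procrustes_distance(base, means[[g]])
  }
  names(means) <- groups
  set.seed(seed)
  records <- list()
  idx <- 0L
  tab <- data.frame(specimen_id = character(), taxon = character(),
                    side = character(), group = character(),
                    stringsAsFactors = FALSE)
  for (g in seq_len(G)) for (i in seq_len(n_per_group)) {
    idx <- idx + 1L
    id <- sprintf("%s_%02d", groups[g], i)
    pts <- means[[g]] +
      matrix(rnorm(2 * nrow(base), sd = noise_sd), ncol = 2)
    records[[idx]] <- list(id = id, points = pts, scale = NA_real_,
                           image = NA_character_)
    tab <- rbind(tab, data.frame(specimen_id = id,
                                 taxon = paste0(groups[g], "_taxon"),
                                 side = "left", group = groups[g],
                                 stringsAsFactors = FALSE))
  }
  records <- structure(records, class = "tps_records")
  if (!is.null(tps_path)) write_tps(records, tps_path)
  if (!is.null(csv_path))
    write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  list(records = records, groups = tab, group_means = means,
       delta_realized = delta_real)
}

#' Generate synthetic angle-of-curvature measurements
#'
#' Gaussian draws per group, truncated to (0, 180) degrees. Defaults
#' emulate the postural dichotomy: a straight-radius group centred on 90
#' degrees and a curved-radius group centred on 75 degrees, both with 5
#' degrees of spread.
#'
#' @param n_per_group observations per group (default 30).
#' @param means named vector of group mean angles in degrees
#'   (default `c(sprawled = 90, parasagittal = 75)`).
#' @param sd common standard deviation in degrees (default 5).
#' @param seed integer seed.
#' @param csv_path optional output CSV path.
#' @return data.frame with `specimen_id`, `group`, `angle_deg`.
#' @export
generate_angles <- function(n_per_group = 30,
                            means = c(sprawled = 90, parasagittal = 75),
                            sd = 5, seed = 1, csv_path = NULL) {
  if (sd < 0) stop("sd must be >= 0")
  if (any(means <= 0 | means >= 180)) stop("means must lie in (0, 180)")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(means), function(g) {
    draws <- numeric(0)
    while (length(draws) < n_per_group) {
      x <- rnorm(n_per_group, means[[g]], sd)
      draws <- c(draws, x[x > 0 & x < 180])
    }
    data.frame(specimen_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
               group = g, angle_deg = draws[seq_len(n_per_group)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(csv_path))
    write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  out
}

#' Simulate an ultrametric tree with Brownian or white-noise tip traits
#'
#' Pure-birth (Yule) ultrametric tree via [ape::rphylo()]; traits either by
#' Brownian motion along its branches ([ape::rTraitCont()]) or i.i.d.
#' standard normal draws with no tree structure.
#'
#' @param n_tips number of tips (>= 4).
#' @param mode `"BM"` or `"white"`.
#' @param seed integer seed.
#' @param newick_path optional path to write the tree in newick format.
#' @return list with `tree` (`phylo`) and `traits` (named numeric).
#' @export
generate_tree_and_traits <- function(n_tips, mode = c("BM", "white"),
                                     seed = 1, newick_path = NULL) {
  if (n_tips < 4) stop("need at least 4 tips")
  mode <- match.arg(mode)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  traits <- if (mode == "BM")
    ape::rTraitCont(tree, model = "BM", sigma = 1)
  else {
    tr <- rnorm(n_tips)
    names(tr) <- tree$tip.label
    tr
  }
  if (!is.null(newick_path)) ape::write.tree(tree, newick_path)
  list(tree = tree, traits = traits)
}
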