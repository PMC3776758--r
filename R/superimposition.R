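# Partial Procrustes generalized superimposition with optional
# minimum-bending-energy sliding of semi-landmarks.
#
# "Partial" superimposition: translation, rotation and isometric size are
# removed, and every configuration (including the consensus) is held at
# centroid size exactly 1 — size is not re-optimized during rotation.
# Rotation is solved in closed form via complex arithmetic; reflections are
# never allowed (sides are standardized by mirroring at load time).

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid — the size measure removed by Procrustes scaling.
#'
#' @param points k x 2 coordinate matrix.
#' @return positive scalar; 0 (with a warning) when all points coincide.
#' @export
centroid_size <- function(points) {
  .check_config(points)
  ctr <- colMeans(points)
  cs <- sqrt(sum(sweep(points, 2, ctr)^2))
  if (cs == 0) warning("degenerate configuration: all landmarks coincide")
  cs
}

#' Centre a configuration at the origin and scale to unit centroid size
#'
#' @param points k x 2 coordinate matrix.
#' @return k x 2 matrix with centroid (0, 0) and centroid size 1.
#' @export
center_and_scale <- function(points) {
  .check_config(points)
  z <- .normalize_cx(.as_cx(points))
  out <- .cx_as_mat(z)
  attributes(out) <- attributes(points)
  dim(out) <- c(nrow(points), 2)
  out
}

#' Optimal rotation of one normalized configuration onto another
#'
#' Finds the least-squares rotation (closed form, rotation only — no
#' reflection) of `b` onto `a`, both already centred and scaled to unit
#' centroid size, and the resulting partial Procrustes distance.
#'
#' @param a,b k x 2 centred, unit-centroid-size configurations with equal k.
#' @return list with `angle` (radians, counter-clockwise, applied to `b`),
#'   `aligned` (rotated `b`) and `distance` (root summed squared coordinate
#'   difference after rotation).
#' @export
align_pair <- function(a, b) {
  .check_config(a, "a"); .check_config(b, "b")
  if (nrow(a) != nrow(b)) stop("landmark count mismatch")
  fit <- .fit_cx(.as_cx(a), .as_cx(b))
  list(angle = fit$angle, aligned = .cx_as_mat(fit$z),
       distance = fit$distance)
}

#' Partial Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size, one is
#' optimally rotated onto the other, and the root summed squared coordinate
#' difference is returned. Symmetric in its arguments.
#'
#' @param a,b k x 2 coordinate matrices with equal k.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  .check_config(a, "a"); .check_config(b, "b")
  if (nrow(a) != nrow(b)) stop("landmark count mismatch")
  .pdist_cx(.normalize_cx(.as_cx(a)), .normalize_cx(.as_cx(b)))
}

# one GPA sweep on a complex n x k matrix of normalized configs:
# align all rows to consensus, recompute consensus as the re-normalized mean
.gpa_sweep <- function(Z, cons) {
  # optimal rotation of row i onto cons has angle Arg(sum(Conj(Z_i) cons))
  s <- Conj(Z %*% Conj(cons))        # n x 1 complex inner products
  rot <- exp(1i * Arg(s))
  Z <- Z * as.vector(rot)
  new_cons <- .normalize_cx(colMeans(Z))
  # pin orientation: rotate the new consensus (and all specimens with it)
  # onto the previous one, so the solution cannot drift along the
  # rotational orbit of equivalent superimpositions
  ang <- Arg(sum(Conj(new_cons) * cons))
  new_cons <- new_cons * exp(1i * ang)
  Z <- Z * exp(1i * ang)
  list(Z = Z, cons = new_cons)
}

.gpa_iterate <- function(Z, cons, tol, max_iter) {
  iters <- 0L; converged <- FALSE
  repeat {
    iters <- iters + 1L
    sw <- .gpa_sweep(Z, cons)
    delta <- sqrt(mean(Mod(sw$cons - cons)^2))
    Z <- sw$Z; cons <- sw$cons
    if (delta < tol) { converged <- TRUE; break }
    if (iters >= max_iter) break
  }
  list(Z = Z, cons = cons, iterations = iters, converged = converged)
}

#' Generalized Procrustes analysis (partial superimposition)
#'
#' Iteratively superimposes all specimens: normalize each to centroid size
#' 1, rotate each onto the current consensus, recompute the consensus as
#' the re-normalized coordinate-wise mean, and repeat until the root mean
#' square change in the consensus falls below `tol`. With `slide = TRUE`,
#' passes of minimum-bending-energy semi-landmark sliding (see
#' [slide_semilandmarks()]) are interleaved: `slide_cycles` outer cycles of
#' (slide, re-superimpose), then a final superimposition.
#'
#' @param x k x 2 x n coordinate array, `tps_records`, or list of matrices.
#' @param slide slide semi-landmarks by the minimum bending energy
#'   criterion (default `FALSE`).
#' @param fixed index of the fixed landmark that never slides (default 1).
#' @param tol RMS consensus-change convergence tolerance (default 1e-8).
#' @param max_iter maximum alignment iterations per superimposition
#'   (default 100).
#' @param slide_cycles outer slide/re-superimpose cycles (default 3).
#' @return object of class `gpa_result`: `consensus` (k x 2, centroid size
#'   1), `aligned` (k x 2 x n), `distances` (partial Procrustes distance of
#'   each specimen to the consensus), `iterations`, `converged`, `slid`.
#' @export
gpa <- function(x, slide = FALSE, fixed = 1L, tol = 1e-8, max_iter = 100,
                slide_cycles = 3) {
  arr <- if (is.array(x) && length(dim(x)) == 3) x else coords_array(x)
  n <- dim(arr)[3]; k <- dim(arr)[1]
  if (n < 2) stop("GPA needs at least 2 specimens")
  Z <- t(vapply(seq_len(n),
                function(i) .normalize_cx(.as_cx(arr[, , i])),
                complex(k)))
  cons <- .normalize_cx(colMeans(.gpa_sweep(Z, Z[1, ])$Z))
  res <- .gpa_iterate(Z, cons, tol, max_iter)
  total_iters <- res$iterations
  if (slide) {
    if (k < 4) stop("sliding needs at least 4 landmarks")
    for (cyc in seq_len(slide_cycles)) {
      cons_mat <- .cx_as_mat(res$cons)
      B <- bending_energy_matrix(cons_mat)$bending_energy
      sl <- .slide_all(res$Z, res$cons, B, fixed)
      res <- .gpa_iterate(sl, res$cons, tol, max_iter)
      total_iters <- total_iters + res$iterations
    }
    res <- .gpa_iterate(res$Z, res$cons, tol, max_iter)
    total_iters <- total_iters + res$iterations
  }
  if (!res$converged)
    warning("GPA did not converge within max_iter iterations")
  # canonical output orientation: rotate the whole solution so the
  # consensus' fixed landmark lies on the positive x-axis; output is then
  # invariant to any common rotation of the raw data
  phi <- Arg(res$cons[fixed])
  res$cons <- res$cons * exp(-1i * phi)
  res$Z <- res$Z * exp(-1i * phi)
  aligned <- array(NA_real_, dim = c(k, 2, n), dimnames = dimnames(arr))
  for (i in seq_len(n)) aligned[, , i] <- .cx_as_mat(res$Z[i, ])
  distances <- vapply(seq_len(n),
                      function(i) .pdist_cx(res$cons, res$Z[i, ]),
                      numeric(1))
  names(distances) <- dimnames(arr)[[3]]
  structure(list(consensus = .cx_as_mat(res$cons), aligned = aligned,
                 distances = distances, iterations = total_iters,
                 converged = res$converged, slid = slide),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat("Partial Procrustes superimposition:",
      dim(x$aligned)[3], "specimens,", dim(x$aligned)[1], "landmarks\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)",
      if (x$slid) "with semi-landmark sliding" else "", "\n")
  cat("  Procrustes distances to consensus: mean",
      format(mean(x$distances), digits = 4), ", max",
      format(max(x$distances), digits = 4), "\n")
  invisible(x)
}

# slide every row of complex matrix Z against complex consensus; returns Z.
# Asserts per pass that sliding did not increase total bending energy
# (checked before the re-normalization that restores centroid size 1).
.slide_all <- function(Z, cons, B, fixed) {
  cons_mat <- .cx_as_mat(cons)
  be_pre <- 0; be_post <- 0
  for (i in seq_len(nrow(Z))) {
    cfg <- .cx_as_mat(Z[i, ])
    sl <- .slide_one(cfg, cons_mat, B, fixed)
    be_pre <- be_pre + bending_energy(cons_mat, cfg, B)
    be_post <- be_post + bending_energy(cons_mat, sl$points, B)
    Z[i, ] <- .normalize_cx(.as_cx(sl$points))
  }
  if (be_post > be_pre + 1e-8 * (1 + be_pre))
    warning("sliding pass increased total bending energy")
  Z
}

# slide one configuration; tangents are cyclic central differences of the
# specimen's own outline; the fixed landmark participates as a neighbour
# but never moves. Minimizes the TPS bending energy of the deformation
# consensus -> slid configuration over signed sliding amounts t.
.slide_one <- function(cfg, cons, B, fixed) {
  k <- nrow(cfg)
  sliders <- setdiff(seq_len(k), fixed)
  nxt <- c(2:k, 1L); prv <- c(k, 1:(k - 1L))
  tang <- cfg[nxt, , drop = FALSE] - cfg[prv, , drop = FALSE]
  tlen <- sqrt(rowSums(tang^2))
  tlen[tlen == 0] <- 1
  tang <- tang / tlen
  tx <- tang[sliders, 1]; ty <- tang[sliders, 2]
  rx <- cfg[, 1] - cons[, 1]; ry <- cfg[, 2] - cons[, 2]
  Bss <- B[sliders, sliders, drop = FALSE]
  M <- Bss * (outer(tx, tx) + outer(ty, ty))
  rhs <- tx * (B %*% rx)[sliders] + ty * (B %*% ry)[sliders]
  t_amt <- tryCatch(solve(M, -rhs), error = function(e) {
    warning("singular sliding system; using ridge-regularized solve")
    solve(M + diag(1e-10, nrow(M)), -rhs)
  })
  out <- cfg
  out[sliders, 1] <- cfg[sliders, 1] + t_amt * tx
  out[sliders, 2] <- cfg[sliders, 2] + t_amt * ty
  list(points = out, amounts = t_amt)
}

#' Slide semi-landmarks by the minimum bending energy criterion
#'
#' For each specimen, every semi-landmark (all points except `fixed`) moves
#' only along its tangent direction (cyclic central difference of its
#' neighbours on the closed outline, taken on the specimen's current
#' configuration); the signed sliding amounts jointly minimize the
#' thin-plate-spline bending energy of the deformation from the consensus
#' to the slid configuration. The fixed landmark never moves.
#'
#' @param aligned k x 2 x n array of Procrustes-aligned configurations (or
#'   a single k x 2 matrix).
#' @param consensus k x 2 consensus configuration.
#' @param fixed index of the non-sliding landmark (default 1).
#' @param renormalize re-centre and re-scale slid configurations to
#'   centroid size 1 (default `TRUE`).
#' @return array (or matrix) of slid configurations; attribute
#'   `sliding_amounts` holds the per-specimen signed amounts.
#' @export
slide_semilandmarks <- function(aligned, consensus, fixed = 1L,
                                renormalize = TRUE) {
  single <- is.matrix(aligned)
  if (single) aligned <- array(aligned, dim = c(dim(aligned), 1))
  k <- dim(aligned)[1]
  if (k < 4) stop("sliding needs at least 4 landmarks")
  B <- bending_energy_matrix(consensus)$bending_energy
  out <- aligned
  amounts <- matrix(NA_real_, dim(aligned)[3], k - 1L)
  for (i in seq_len(dim(aligned)[3])) {
    sl <- .slide_one(aligned[, , i], consensus, B, fixed)
    pts <- sl$points
    if (renormalize) pts <- center_and_scale(pts)
    out[, , i] <- pts
    amounts[i, ] <- sl$amounts
  }
  if (single) out <- out[, , 1]
  attr(out, "sliding_amounts") <- amounts
  out
}

#' Thin-plate-spline bending energy of a deformation
#'
#' Quadratic-form bending energy of the deformation taking `reference` to
#' `config`, evaluated against the bending energy matrix computed at the
#' reference: `t(dx) B dx + t(dy) B dy` for displacements d. Zero for any
#' purely affine displacement field.
#'
#' @param reference k x 2 reference (consensus) configuration.
#' @param config k x 2 target configuration.
#' @param B optional precomputed bending energy matrix at `reference`.
#' @return non-negative scalar.
#' @export
bending_energy <- function(reference, config, B = NULL) {
  if (is.null(B)) B <- bending_energy_matrix(reference)$bending_energy
  dx <- config[, 1] - reference[, 1]
  dy <- config[, 2] - reference[, 2]
  max(0, as.numeric(t(dx) %*% B %*% dx + t(dy) %*% B %*% dy))
}

#' Export aligned coordinates in long format
#'
#' @param g a `gpa_result`.
#' @return data.frame with `specimen_id`, `landmark`, `x`, `y`.
#' @export
aligned_long <- function(g) {
  stopifnot(inherits(g, "gpa_result"))
  n <- dim(g$aligned)[3]; k <- dim(g$aligned)[1]
  ids <- dimnames(g$aligned)[[3]]
  if (is.null(ids)) ids <- paste0("specimen_", seq_len(n))
  data.frame(specimen_id = rep(ids, each = k),
             landmark = rep(seq_len(k), n),
             x = as.vector(g$aligned[, 1, ]),
             y = as.vector(g$aligned[, 2, ]))
}
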