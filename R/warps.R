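# Thin-plate-spline warp analysis: bending energy matrix, principal warps,
# partial warp scores, relative warps (PCA of the score matrix) and the
# broken-stick assessment of axis variance.
#
# Kernel convention: U(r) = r^2 log(r^2) (Bookstein), U(0) = 0. The
# alternative r^2 log r rescales eigenvalues by 1/2 but leaves warp
# directions — and hence all scores and ordinations — unchanged.

#' Bending energy matrix and principal warps at a consensus shape
#'
#' Builds the standard 2D thin-plate-spline system
#' `L = [[K, Q], [Q', 0]]` with `K[i,j] = U(r_ij)`, `U(r) = r^2 log(r^2)`,
#' and `Q = [1 | x | y]`; the bending energy matrix is the upper-left
#' k x k block of `L^-1`. Its eigenvectors with positive eigenvalue are the
#' principal warps (k - 3 of them for a non-degenerate consensus); it
#' annihilates the affine subspace spanned by 1, x and y.
#'
#' @param consensus k x 2 configuration with no duplicated landmarks.
#' @return object of class `warp_basis`: `bending_energy` (k x k),
#'   `principal_warps` (k x (k-3), descending eigenvalue order),
#'   `eigenvalues`.
#' @export
bending_energy_matrix <- function(consensus) {
  .check_config(consensus, "consensus")
  k <- nrow(consensus)
  if (k < 3) stop("need at least 3 landmarks")
  d <- as.matrix(dist(consensus))
  if (any(d[upper.tri(d)] < 1e-12)) {
    idx <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("duplicate landmarks ", idx[1], " and ", idx[2],
         ": thin-plate spline system is singular")
  }
  K <- ifelse(d > 0, d^2 * log(d^2), 0)
  Q <- cbind(1, consensus)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Linv <- solve(L)
  B <- Linv[1:k, 1:k, drop = FALSE]
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(1e-12, max(eig$values) * 1e-9)
  pos <- which(eig$values > tol)
  structure(list(bending_energy = B,
                 principal_warps = eig$vectors[, pos, drop = FALSE],
                 eigenvalues = eig$values[pos]),
            class = "warp_basis")
}

# orthonormal basis (2k x m) of the non-uniform shape subspace: principal
# warps placed in x and y blocks (stacking convention: v = c(vx, vy))
.nonuniform_basis <- function(basis) {
  W <- basis$principal_warps
  k <- nrow(W); m <- ncol(W)
  out <- matrix(0, 2 * k, 2 * m)
  for (j in seq_len(m)) {
    out[1:k, 2 * j - 1] <- W[, j]
    out[(k + 1):(2 * k), 2 * j] <- W[, j]
  }
  out
}

# orthonormal basis (2k x 2) of the uniform (affine, non-similarity) shape
# subspace at the consensus: the orthogonal complement, within R^{2k}, of
# the similarity directions (two translations, rotation, scaling) plus the
# non-uniform warp subspace.
.uniform_basis <- function(consensus, basis) {
  k <- nrow(consensus)
  cx <- consensus[, 1]; cy <- consensus[, 2]
  sim <- cbind(c(rep(1, k), rep(0, k)),
               c(rep(0, k), rep(1, k)),
               c(-cy, cx),
               c(cx, cy))
  M <- cbind(sim, .nonuniform_basis(basis))
  sv <- svd(M, nu = 2 * k)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  U <- sv$u[, (rank + 1):(2 * k), drop = FALSE]
  if (ncol(U) != 2)
    stop("uniform subspace has dimension ", ncol(U), ", expected 2")
  # deterministic sign: largest-magnitude entry positive
  for (j in 1:2) if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  U
}

#' Partial warp scores of Procrustes-aligned specimens
#'
#' Projects each specimen's Procrustes residual (aligned minus consensus)
#' onto the principal warps, separately in x and y, giving 2(k-3) columns
#' of non-uniform scores; with `include_uniform = TRUE` (the default) two
#' further columns hold the projection onto an orthonormal basis of the
#' uniform (affine) shape subspace at the consensus. Equal weighting of the
#' warps (the alpha = 0 convention) is used throughout, so a PCA of these
#' scores equals a PCA of the residuals restricted to the corresponding
#' subspace.
#'
#' @param g a `gpa_result`.
#' @param basis a `warp_basis` computed at `g$consensus` (computed if
#'   omitted).
#' @param include_uniform append the two uniform-component columns
#'   (default `TRUE`).
#' @return object of class `warp_scores`: `scores` (n x m), `basis_vectors`
#'   (2k x m orthonormal, stacking x over y), `consensus`, `warp_basis`,
#'   `include_uniform`.
#' @export
partial_warp_scores <- function(g, basis = NULL, include_uniform = TRUE) {
  stopifnot(inherits(g, "gpa_result"))
  if (is.null(basis)) basis <- bending_energy_matrix(g$consensus)
  k <- nrow(g$consensus)
  if (nrow(basis$bending_energy) != k)
    stop("warp basis and consensus disagree on landmark count")
  V <- .nonuniform_basis(basis)
  if (include_uniform)
    V <- cbind(V, .uniform_basis(g$consensus, basis))
  n <- dim(g$aligned)[3]
  resid <- t(vapply(seq_len(n), function(i)
    c(g$aligned[, 1, i] - g$consensus[, 1],
      g$aligned[, 2, i] - g$consensus[, 2]), numeric(2 * k)))
  scores <- resid %*% V
  rownames(scores) <- dimnames(g$aligned)[[3]]
  colnames(scores) <- c(paste0(rep(paste0("PW", seq_len(ncol(
    basis$principal_warps))), each = 2), c("x", "y")),
    if (include_uniform) c("U1", "U2"))
  structure(list(scores = scores, basis_vectors = V,
                 consensus = g$consensus, warp_basis = basis,
                 include_uniform = include_uniform),
            class = "warp_scores")
}

#' Relative warp analysis (PCA of the partial warp score matrix)
#'
#' Eigen-decomposition of the covariance matrix of the column-centred
#' partial warp scores. Axes are returned in descending eigenvalue order;
#' each loading's largest-magnitude entry is made positive so output is
#' reproducible across eigen-solvers.
#'
#' @param pw a `warp_scores` object (n >= 3 specimens).
#' @return object of class `relative_warps`: `scores` (n x m, centred,
#'   mutually orthogonal columns), `loadings` (columns are axes in partial
#'   warp score space), `eigenvalues`, `variance_proportions` (sum to 1),
#'   plus `pw` (the input, for shape reconstruction) and `center` (the
#'   partial-warp column means).
#' @export
relative_warps <- function(pw) {
  stopifnot(inherits(pw, "warp_scores"))
  X <- pw$scores
  n <- nrow(X)
  if (n < 3) stop("relative warp analysis needs at least 3 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  cv <- crossprod(Xc) / (n - 1)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs)))
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  scores <- Xc %*% vecs
  colnames(scores) <- paste0("RW", seq_len(ncol(scores)))
  rownames(scores) <- rownames(X)
  colnames(vecs) <- colnames(scores)
  structure(list(scores = scores, loadings = vecs, eigenvalues = vals,
                 variance_proportions = vals / sum(vals),
                 pw = pw, center = ctr),
            class = "relative_warps")
}

#' @export
print.relative_warps <- function(x, ...) {
  vp <- x$variance_proportions
  cat("Relative warps:", nrow(x$scores), "specimens,",
      ncol(x$scores), "axes\n")
  cat("  variance proportions (first 5):",
      paste(format(100 * vp[seq_len(min(5, length(vp)))], digits = 4),
            collapse = "% "), "%\n")
  invisible(x)
}

#' Broken-stick expected variance proportions
#'
#' Expected proportion of variance for each of S axes when total variance
#' is partitioned at random: `E(p_k) = (1/S) * sum_{i=k}^{S} 1/i`. An
#' observed axis summarizing more than its broken-stick expectation is
#' conventionally read as carrying non-random structure.
#'
#' @param S number of axes (>= 1).
#' @return numeric vector of length S, descending, summing to 1.
#' @export
broken_stick <- function(S) {
  if (S < 1) stop("S must be at least 1")
  S <- as.integer(S)
  vapply(seq_len(S), function(k) sum(1 / (k:S)) / S, numeric(1))
}

#' Reconstruct the shape at a position along a relative warp axis
#'
#' Maps a score on one relative warp axis back to landmark coordinates:
#' consensus + score_value * (axis loading carried through the orthonormal
#' warp basis). Linear in `score_value`; `score_value = 0` reproduces the
#' consensus exactly.
#'
#' @param rw a `relative_warps` object.
#' @param axis axis number.
#' @param score_value score along that axis.
#' @return k x 2 landmark configuration.
#' @export
shape_along_axis <- function(rw, axis, score_value) {
  stopifnot(inherits(rw, "relative_warps"))
  if (axis < 1 || axis > ncol(rw$loadings)) stop("axis out of range")
  disp <- rw$pw$basis_vectors %*% (score_value * rw$loadings[, axis])
  k <- nrow(rw$pw$consensus)
  rw$pw$consensus + cbind(disp[1:k], disp[(k + 1):(2 * k)])
}

#' Relative warp variance table with broken-stick expectations
#'
#' @param rw a `relative_warps` object.
#' @param axes number of axes to tabulate (default: all with positive
#'   variance).
#' @return data.frame with `axis`, `proportion`, `cumulative`,
#'   `broken_stick_expectation`.
#' @export
variance_table <- function(rw, axes = NULL) {
  vp <- rw$variance_proportions
  S <- sum(vp > 1e-12)
  if (is.null(axes)) axes <- S
  bs <- broken_stick(S)
  data.frame(axis = seq_len(axes),
             proportion = vp[seq_len(axes)],
             cumulative = cumsum(vp)[seq_len(axes)],
             broken_stick_expectation = c(bs, rep(NA, max(0, axes - S)))[
               seq_len(axes)])
}
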