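test_that("three landmarks give an identically zero bending energy matrix", {
  cons <- rbind(c(0, 0), c(1, 0), c(0.3, 0.9))
  wb <- bending_energy_matrix(cons)
  expect_lt(max(abs(wb$bending_energy)), 1e-10)
  expect_equal(ncol(wb$principal_warps), 0)
})

test_that("bending energy annihilates the affine subspace", {
  set.seed(20)
  for (rep in 1:5) {
    cons <- center_and_scale(random_outline(21))
    B <- bending_energy_matrix(cons)$bending_energy
    expect_equal(B, t(B), tolerance = 1e-10)
    expect_lt(max(abs(B %*% rep(1, 21))), 1e-8)
    expect_lt(max(abs(B %*% cons[, 1])), 1e-8)
    expect_lt(max(abs(B %*% cons[, 2])), 1e-8)
    # affine displacement fields have zero bending energy
    A <- matrix(rnorm(4), 2); b <- rnorm(2)
    target <- cons %*% A + matrix(b, 21, 2, byrow = TRUE)
    expect_lt(bending_energy(cons, target, B), 1e-8)
  }
})

test_that("a generic consensus has exactly k - 3 positive eigenvalues", {
  set.seed(22)
  for (k in c(8, 13, 21)) {
    wb <- bending_energy_matrix(center_and_scale(random_outline(k)))
    expect_equal(length(wb$eigenvalues), k - 3)
    expect_true(all(wb$eigenvalues > 0))
    expect_equal(ncol(wb$principal_warps), k - 3)
  }
})

test_that("bending energy matches an independent block-inverse construction", {
  # oracle: B = Kinv - Kinv Q (Q' Kinv Q)^-1 Q' Kinv (Schur complement),
  # a different algebraic route from the full-L inverse used internally
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  wb <- bending_energy_matrix(sq)
  d <- as.matrix(dist(sq))
  K <- ifelse(d > 0, d^2 * log(d^2), 0)
  Q <- cbind(1, sq)
  Kinv <- solve(K)
  Bo <- Kinv - Kinv %*% Q %*% solve(t(Q) %*% Kinv %*% Q) %*% t(Q) %*% Kinv
  expect_equal(wb$bending_energy, (Bo + t(Bo)) / 2, tolerance = 1e-8)
  expect_equal(sort(eigen(Bo, symmetric = TRUE)$values,
                    decreasing = TRUE)[1],
               wb$eigenvalues[1], tolerance = 1e-8)
  expect_error(bending_energy_matrix(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "duplicate")
})

test_that("partial warp scores are zero at the consensus and have 2(k-3) columns", {
  set.seed(23)
  arr <- noisy_group(outline_archetype("rounded"), 10, 0.02)
  g <- gpa(arr)
  pw <- partial_warp_scores(g, include_uniform = FALSE)
  expect_equal(ncol(pw$scores), 2 * (21 - 3))
  pwu <- partial_warp_scores(g, include_uniform = TRUE)
  expect_equal(ncol(pwu$scores), 2 * (21 - 3) + 2)
  # a specimen equal to the consensus scores zero on every warp
  arr2 <- g$aligned
  arr2[, , 1] <- g$consensus
  g2 <- g; g2$aligned <- arr2
  pw2 <- partial_warp_scores(g2, include_uniform = TRUE)
  expect_lt(max(abs(pw2$scores[1, ])), 1e-10)
  # mismatched basis is rejected
  wb8 <- bending_energy_matrix(center_and_scale(random_outline(8)))
  expect_error(partial_warp_scores(g, basis = wb8), "disagree")
})

test_that("PCA of partial warp scores equals PCA of projected Procrustes residuals", {
  set.seed(24)
  arr <- noisy_group(outline_archetype("reniform"), 10, 0.03)
  g <- gpa(arr)
  pw <- partial_warp_scores(g, include_uniform = FALSE)
  rw <- relative_warps(pw)
  # oracle: residuals projected off the affine + similarity subspace,
  # then a plain covariance PCA in coordinate space
  k <- 21; n <- 10
  resid <- t(sapply(1:n, function(i)
    c(g$aligned[, 1, i] - g$consensus[, 1],
      g$aligned[, 2, i] - g$consensus[, 2])))
  cx <- g$consensus[, 1]; cy <- g$consensus[, 2]
  aff <- cbind(c(rep(1, k), rep(0, k)), c(rep(0, k), rep(1, k)),
               c(cx, rep(0, k)), c(cy, rep(0, k)),
               c(rep(0, k), cx), c(rep(0, k), cy))
  P <- diag(2 * k) - aff %*% solve(crossprod(aff)) %*% t(aff)
  proj <- resid %*% P
  ev <- eigen(cov(proj), symmetric = TRUE)$values
  m <- ncol(pw$scores)
  expect_equal(rw$eigenvalues[1:m], ev[1:m], tolerance = 1e-8)
})

test_that("relative warp proportions are well-formed and duplication-invariant", {
  set.seed(25)
  arr <- noisy_group(outline_archetype("rounded"), 8, 0.02)
  g <- gpa(arr)
  rw <- relative_warps(partial_warp_scores(g))
  expect_equal(sum(rw$variance_proportions), 1, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(rw$scores))), 1e-10)
  # score columns mutually orthogonal (relative to the leading norms;
  # trailing axes of an n < m problem have numerically zero variance)
  G <- crossprod(rw$scores)
  nrm_max <- max(sqrt(diag(G)))
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * nrm_max^2)
  # duplicating every specimen leaves the proportions unchanged
  arr2 <- array(c(arr, arr), c(21, 2, 16))
  rw2 <- relative_warps(partial_warp_scores(gpa(arr2)))
  expect_equal(rw2$variance_proportions, rw$variance_proportions,
               tolerance = 1e-6)
})

test_that("relative warp eigenvalues match a brute-force covariance solve", {
  set.seed(26)
  arr <- noisy_group(outline_archetype("rounded"), 9, 0.02)
  g <- gpa(arr)
  pw <- partial_warp_scores(g)
  rw <- relative_warps(pw)
  ev <- eigen(cov(pw$scores), symmetric = TRUE)$values
  expect_equal(rw$eigenvalues, pmax(ev, 0), tolerance = 1e-9)
  expect_error(relative_warps(structure(list(scores = pw$scores[1:2, ]),
                                        class = "warp_scores")),
               "at least 3")
})

test_that("variance proportions are invariant to a joint rotation", {
  set.seed(27)
  arr <- noisy_group(outline_archetype("reniform"), 8, 0.02)
  g <- gpa(arr)
  rw <- relative_warps(partial_warp_scores(g))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g2 <- g
  g2$consensus <- g$consensus %*% R
  for (i in 1:8) g2$aligned[, , i] <- g$aligned[, , i] %*% R
  rw2 <- relative_warps(partial_warp_scores(g2))
  expect_equal(rw2$variance_proportions, rw$variance_proportions,
               tolerance = 1e-9)
})

test_that("broken stick follows the closed form", {
  expect_equal(broken_stick(1), 1)
  expect_equal(broken_stick(3), c(0.6111, 0.2778, 0.1111),
               tolerance = 1e-4)
  for (S in c(2, 5, 17)) {
    bs <- broken_stick(S)
    expect_equal(sum(bs), 1, tolerance = 1e-12)
    expect_true(all(diff(bs) < 0))
  }
  expect_error(broken_stick(0), "at least 1")
})

test_that("shape_along_axis is linear and round-trips through score space", {
  set.seed(28)
  arr <- noisy_group(outline_archetype("rounded"), 10, 0.02)
  g <- gpa(arr)
  rw <- relative_warps(partial_warp_scores(g))
  # score 0 reproduces the consensus exactly
  s0 <- shape_along_axis(rw, 1, 0)
  expect_equal(s0, g$consensus, tolerance = 1e-15)
  # linearity
  s1 <- shape_along_axis(rw, 1, 0.01)
  s2 <- shape_along_axis(rw, 1, 0.02)
  expect_equal(s2 - s0, 2 * (s1 - s0), tolerance = 1e-10)
  # round trip: project the reconstruction back into score space
  v <- 0.015
  sh <- shape_along_axis(rw, 2, v)
  resid <- c(sh[, 1] - g$consensus[, 1], sh[, 2] - g$consensus[, 2])
  pwvec <- as.vector(t(rw$pw$basis_vectors) %*% resid)
  back <- as.vector(t(rw$loadings) %*% pwvec)
  expect_equal(back[2], v, tolerance = 1e-8)
  expect_lt(max(abs(back[-2])), 1e-8)
  expect_error(shape_along_axis(rw, 99, 0), "out of range")
})

test_that("variance_table pairs proportions with broken-stick expectations", {
  set.seed(29)
  arr <- noisy_group(outline_archetype("rounded"), 8, 0.02)
  rw <- relative_warps(partial_warp_scores(gpa(arr)))
  vt <- variance_table(rw, axes = 3)
  expect_equal(nrow(vt), 3)
  expect_equal(vt$proportion, rw$variance_proportions[1:3])
  expect_equal(vt$cumulative[3], sum(rw$variance_proportions[1:3]))
  S <- sum(rw$variance_proportions > 1e-12)
  expect_equal(vt$broken_stick_expectation, broken_stick(S)[1:3])
})
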