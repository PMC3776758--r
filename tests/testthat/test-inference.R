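test_that("goodall_f handles exact-copy and zero-scatter degenerate groups", {
  set.seed(30)
  base <- outline_archetype("rounded")
  same <- shape_array(base, base, base)
  expect_equal(goodall_f(same, same), 0)
  other <- outline_archetype("reniform")
  expect_warning(f <- goodall_f(same, shape_array(other, other, other)),
                 "Inf")
  expect_identical(f, Inf)
  expect_error(goodall_f(shape_array(base), same), "at least 2")
})

test_that("goodall_f matches an independent sums-of-squares oracle", {
  set.seed(1)
  a <- noisy_group(outline_archetype("rounded"), 8, 0.01)
  off <- outline_archetype("rounded")
  off[5:9, ] <- off[5:9, ] * 1.06     # archetype offset ~ 0.05
  b <- noisy_group(off, 8, 0.01)
  f <- goodall_f(a, b)
  # oracle: explicit loops over procrustes_distance on the same joint
  # superimposition, plugged into the sums-of-squares definition
  g <- gpa(array(c(a, b), c(21, 2, 16)))
  ma <- center_and_scale(apply(g$aligned[, , 1:8], c(1, 2), mean))
  mb <- center_and_scale(apply(g$aligned[, , 9:16], c(1, 2), mean))
  ssb <- procrustes_distance(ma, mb)^2 / (1 / 8 + 1 / 8)
  ssw <- 0
  for (i in 1:8) ssw <- ssw + procrustes_distance(g$aligned[, , i], ma)^2
  for (i in 9:16) ssw <- ssw + procrustes_distance(g$aligned[, , i], mb)^2
  f_oracle <- ssb / (ssw / (8 + 8 - 2))
  expect_equal(f, f_oracle, tolerance = 1e-9)
})

test_that("goodall_f is invariant to group exchange and common rotation", {
  set.seed(31)
  a <- noisy_group(outline_archetype("rounded"), 5, 0.02)
  b <- noisy_group(outline_archetype("reniform"), 6, 0.02)
  f1 <- goodall_f(a, b)
  expect_equal(goodall_f(b, a), f1, tolerance = 1e-9)
  th <- 0.9; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  a2 <- a; b2 <- b
  for (i in 1:5) a2[, , i] <- a[, , i] %*% R
  for (i in 1:6) b2[, , i] <- b[, , i] %*% R
  expect_equal(goodall_f(a2, b2), f1, tolerance = 1e-9)
})

test_that("permutation p matches exhaustive enumeration for 3-vs-3 splits", {
  set.seed(32)
  a <- noisy_group(outline_archetype("rounded"), 3, 0.005)
  b <- noisy_group(outline_archetype("reniform"), 3, 0.005)
  pooled <- array(c(a, b), c(21, 2, 6))
  labels <- rep(c("A", "B"), each = 3)
  res <- permutation_test(pooled, labels, seed = 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 20)
  # full enumeration oracle, written independently over all 20 splits
  g <- gpa(pooled)
  Z <- t(sapply(1:6, function(i) {
    z <- complex(real = g$aligned[, 1, i], imaginary = g$aligned[, 2, i])
    z <- z - mean(z); z / sqrt(sum(Mod(z)^2))
  }))
  fstat <- function(ia) {
    ms <- lapply(list(ia, setdiff(1:6, ia)), function(idx) {
      m <- colMeans(Z[idx, , drop = FALSE])
      m <- m - mean(m); m / sqrt(sum(Mod(m)^2))
    })
    d2 <- function(u, v) max(0, 2 - 2 * Mod(sum(Conj(u) * v)))
    ssw <- sum(sapply(ia, function(i) d2(Z[i, ], ms[[1]]))) +
      sum(sapply(setdiff(1:6, ia), function(i) d2(Z[i, ], ms[[2]])))
    (d2(ms[[1]], ms[[2]]) / (2 / 3)) / (ssw / 4)
  }
  all_f <- combn(6, 3, fstat)
  obs <- fstat(1:3)
  expect_equal(res$statistic, obs, tolerance = 1e-9)
  expect_equal(res$p_value, mean(all_f >= obs - 1e-12))
  # complete separation: only the true split and its complement reach obs
  expect_equal(res$p_value, 2 / 20)
})

test_that("permutation p-values are bounded, reproducible, and calibrated", {
  set.seed(33)
  arr <- noisy_group(outline_archetype("rounded"), 16, 0.02)
  labels <- rep(c("A", "B"), each = 8)
  r1 <- permutation_test(arr, labels, n_permutations = 199, seed = 42)
  r2 <- permutation_test(arr, labels, n_permutations = 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  expect_warning(permutation_test(arr, labels, n_permutations = 50,
                                  seed = 1), "coarse")

  # type-I calibration: identically distributed groups, 500 simulations
  base <- outline_archetype("rounded")
  k <- nrow(base)
  hits <- 0L
  set.seed(99)
  for (s in 1:500) {
    arr <- noisy_group(base, 12, 0.02)
    res <- permutation_test(arr, rep(c("A", "B"), each = 6),
                            n_permutations = 99, seed = s,
                            exhaustive_limit = 0)
    if (res$p_value <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.03)
  expect_lte(hits / 500, 0.07)
})

test_that("the pairwise battery applies the Bonferroni correction of the field", {
  # 8 groups -> 28 pairs -> corrected level 0.0018 (two significant figures)
  expect_equal(signif(bonferroni_alpha(8), 2), 0.0018)
  expect_equal(signif(bonferroni_alpha(7), 2), 0.0024)
  set.seed(34)
  gens <- generate_outlines(n_per_group = 4, delta = 0.1, noise_sd = 0.01,
                            groups = c("g1", "g2", "g3"), seed = 11)
  arr <- coords_array(gens$records)
  pw <- pairwise_shape_tests(arr, gens$groups$group,
                             n_permutations = 99, seed = 5)
  expect_equal(pw$alpha_corrected, 0.05 / 3)
  expect_equal(pw$F, t(pw$F))
  expect_equal(pw$p, t(pw$p))
  expect_true(all(is.na(diag(pw$F))))
  # a singleton group is skipped with a warning per pair, not an error
  labs <- c(gens$groups$group[-1], "loner")
  w <- capture_warnings(pw2 <- pairwise_shape_tests(arr, labs,
                                                    n_permutations = 99,
                                                    seed = 5))
  expect_length(w, 3)
  expect_true(all(grepl("skipped", w)))
  expect_true(all(is.na(pw2$F["loner", setdiff(rownames(pw2$F),
                                               "loner")])))
})

test_that("kruskal_wallis_mc reproduces the textbook H and exact pair p", {
  # tie-free toy: H from the classic formula
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("A", "B", "C"), each = 3)
  kw <- kruskal_wallis_mc(vals, grp)
  N <- 9; rbar <- c(2, 5, 8)
  H_hand <- 12 / (N * (N + 1)) * sum(3 * (rbar - 5)^2)
  expect_equal(kw$H, H_hand, tolerance = 1e-10)
  expect_equal(unname(kw$mean_ranks), rbar)
  # fully separated 3 vs 3: exact two-sided rank-sum enumeration gives 0.1
  kw2 <- kruskal_wallis_mc(c(1, 2, 3, 10, 11, 12),
                           rep(c("A", "B"), each = 3))
  expect_equal(kw2$p["A", "B"], 0.1)
  expect_equal(kw2$p["A", "B"],
               wilcox.test(c(1, 2, 3), c(10, 11, 12),
                           exact = TRUE)$p.value)
  # constant data: H = 0, nothing significant
  kw3 <- kruskal_wallis_mc(rep(5, 8), rep(c("A", "B"), each = 4))
  expect_equal(kw3$H, 0)
  expect_false(any(kw3$significant, na.rm = TRUE))
  expect_error(kruskal_wallis_mc(1:3, c("A", "A", "B")), "at least 2")
})

test_that("kruskal_wallis_mc decision criterion follows the mean-rank rule", {
  set.seed(35)
  vals <- c(rnorm(10, 0), rnorm(10, 0.2), rnorm(10, 5))
  grp <- rep(c("a", "b", "c"), each = 10)
  kw <- kruskal_wallis_mc(vals, grp)
  zc <- qnorm(1 - kw$alpha_corrected / 2)
  N <- 30
  se <- sqrt(N * (N + 1) / 12 * (1 / 10 + 1 / 10))
  expect_equal(unname(kw$critical["a", "b"]), zc * se)
  expect_equal(unname(kw$significant["a", "c"]),
               unname(kw$diff["a", "c"] > kw$critical["a", "c"]))
  expect_true(kw$significant["a", "c"])
  expect_false(kw$significant["a", "b"])
})

test_that("blomberg_k matches phytools on a fixed dataset", {
  tt <- generate_tree_and_traits(32, "BM", seed = 8)
  ours <- blomberg_k(tt$tree, tt$traits, n_permutations = 0)
  ref <- phytools::phylosig(tt$tree, tt$traits, method = "K")
  k_ref <- if (is.list(ref)) ref$K else as.numeric(ref)
  expect_equal(ours$statistic, k_ref, tolerance = 1e-8)
  expect_error(blomberg_k(tt$tree, setNames(rep(1, 32),
                                            tt$tree$tip.label)),
               "zero variance")
  # missing tips rejected
  expect_error(blomberg_k(tt$tree, tt$traits[-1]), "missing")
})

test_that("blomberg_k permutation p is seeded and flags Brownian signal", {
  tt <- generate_tree_and_traits(32, "BM", seed = 9)
  r1 <- blomberg_k(tt$tree, tt$traits, n_permutations = 199, seed = 7)
  r2 <- blomberg_k(tt$tree, tt$traits, n_permutations = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
  ww <- generate_tree_and_traits(32, "white", seed = 9)
  rw <- blomberg_k(ww$tree, ww$traits, n_permutations = 199, seed = 7)
  expect_lt(rw$statistic, r1$statistic)
})

test_that("multivariate_k reduces to blomberg_k on a single axis", {
  tt <- generate_tree_and_traits(24, "BM", seed = 10)
  single <- matrix(tt$traits, ncol = 1,
                   dimnames = list(names(tt$traits), "RW1"))
  mk <- multivariate_k(tt$tree, single, n_permutations = 99, seed = 3)
  bk <- blomberg_k(tt$tree, tt$traits, n_permutations = 99, seed = 3)
  expect_equal(mk$per_axis$K, bk$statistic, tolerance = 1e-12)
  expect_equal(mk$summary_k, bk$statistic, tolerance = 1e-12)
  # zero-variance axes are skipped with a warning
  two <- cbind(single, RW2 = 0)
  expect_warning(mk2 <- multivariate_k(tt$tree, two, n_permutations = 0),
                 "zero-variance")
  expect_equal(nrow(mk2$per_axis), 1)
})
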