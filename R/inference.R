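# Group-difference and phylogenetic-signal statistics: Goodall's F with
# label-permutation tests on partial Procrustes distances, the pairwise
# battery with Bonferroni control, Kruskal-Wallis multiple comparisons for
# the angle data, and Blomberg's K.

# Fast Goodall's F on an n x k complex matrix of aligned unit
# configurations; ia indexes group A rows. Group means are re-normalized
# coordinate means; distances are partial Procrustes (closed form).
.fast_goodall <- function(Z, ia) {
  A <- Z[ia, , drop = FALSE]
  B <- Z[-ia, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  ma <- .normalize_cx(colMeans(A))
  mb <- .normalize_cx(colMeans(B))
  d2ab <- max(0, 2 - 2 * Mod(sum(Conj(ma) * mb)))
  da2 <- pmax(0, 2 - 2 * Mod(A %*% Conj(ma)))
  db2 <- pmax(0, 2 - 2 * Mod(B %*% Conj(mb)))
  ssw <- sum(da2) + sum(db2)
  num <- d2ab / (1 / na + 1 / nb)
  # squared distances of truly identical shapes bottom out near 1e-15
  # (unit inner products carry ~1e-15 of rounding), so "zero" scatter is
  # judged against that floor, per specimen
  eps <- (na + nb) * 1e-13
  if (ssw < eps) {
    if (num < eps) return(0)
    warning("zero within-group variation with differing means; F = Inf")
    return(Inf)
  }
  num / (ssw / (na + nb - 2))
}

.to_cx_matrix <- function(arr) {
  n <- dim(arr)[3]
  t(vapply(seq_len(n), function(i) .normalize_cx(.as_cx(arr[, , i])),
           complex(dim(arr)[1])))
}

#' Goodall's F statistic for two groups of configurations
#'
#' Ratio of between-group to within-group Procrustes sums of squares:
#' `F = [d2(mean_a, mean_b) / (1/na + 1/nb)] /`
#' `[(sum d2(a_i, mean_a) + sum d2(b_j, mean_b)) / (na + nb - 2)]`,
#' where d is the partial Procrustes distance and group means are the
#' Procrustes means after joint superimposition of the two groups.
#' Because semi-landmarks leave fewer degrees of freedom than coordinates,
#' the statistic is referred to a label-permutation null
#' ([permutation_test()]), never to a parametric F distribution.
#'
#' @param group_a,group_b k x 2 x n coordinate arrays (n >= 2 each, same
#'   k).
#' @param superimpose run a joint GPA on the pooled specimens first
#'   (default `TRUE`; set `FALSE` if inputs are already jointly aligned).
#' @return the F statistic (`Inf`, with a warning, when within-group
#'   variation is exactly zero but the means differ).
#' @export
goodall_f <- function(group_a, group_b, superimpose = TRUE) {
  if (dim(group_a)[3] < 2 || dim(group_b)[3] < 2)
    stop("each group needs at least 2 specimens")
  if (dim(group_a)[1] != dim(group_b)[1])
    stop("landmark count mismatch between groups")
  na <- dim(group_a)[3]
  pooled <- array(c(group_a, group_b),
                  dim = c(dim(group_a)[1], 2, na + dim(group_b)[3]))
  Z <- if (superimpose) .aligned_cx(pooled) else .to_cx_matrix(pooled)
  .fast_goodall(Z, seq_len(na))
}

# joint GPA (no sliding) returning the aligned complex matrix
.aligned_cx <- function(arr) {
  g <- gpa(arr, slide = FALSE)
  .to_cx_matrix(g$aligned)
}

#' Permutation test of a two-group shape difference
#'
#' Tests the observed Goodall's F against the distribution obtained by
#' shuffling group labels over the pooled, jointly superimposed specimens
#' (the superimposition is held fixed across permutations; only labels
#' move). With `n_permutations` random shuffles the p-value is
#' `(1 + #(F_perm >= F_obs)) / (1 + n_permutations)`, so p is never zero;
#' when the number of distinct label splits is at most `exhaustive_limit`
#' every split is enumerated instead and p is the exact tail proportion.
#'
#' @param coords k x 2 x n pooled coordinate array.
#' @param labels length-n vector with exactly two distinct values.
#' @param n_permutations random permutations (default 1999; < 99 draws a
#'   warning).
#' @param seed integer seed for the label shuffles.
#' @param superimpose joint GPA first (default `TRUE`).
#' @param exhaustive_limit enumerate all splits when their count is at most
#'   this (default 10000).
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return object of class `shape_test`: `statistic`, `p_value`,
#'   `n_per_group`, `n_permutations`, `seed`, `significant`, `method`.
#' @export
permutation_test <- function(coords, labels, n_permutations = 1999,
                             seed = NULL, superimpose = TRUE,
                             exhaustive_limit = 10000, alpha = 0.05) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("permutation_test needs exactly two groups")
  if (n_permutations < 99)
    warning("fewer than 99 permutations gives a coarse p-value")
  n <- dim(coords)[3]
  if (n != length(labels)) stop("labels do not match specimen count")
  Z <- if (superimpose) .aligned_cx(coords) else .to_cx_matrix(coords)
  ia <- which(labels == lev[1])
  obs <- .fast_goodall(Z, ia)
  na <- length(ia)
  n_splits <- choose(n, na)
  if (n_splits <= exhaustive_limit) {
    splits <- combn(n, na)
    fs <- apply(splits, 2, function(idx) .fast_goodall(Z, idx))
    p <- mean(fs >= obs - 1e-12)
    method <- "exhaustive"
    n_used <- ncol(splits)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n, na)
      if (.fast_goodall(Z, idx) >= obs - 1e-12) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_permutations)
    method <- "random"
    n_used <- n_permutations
  }
  structure(list(statistic = obs, p_value = p,
                 n_per_group = c(na, n - na), n_permutations = n_used,
                 seed = seed, significant = p < alpha, alpha = alpha,
                 method = method),
            class = "shape_test")
}

#' @export
print.shape_test <- function(x, ...) {
  lab <- if (grepl("Blomberg", x$method)) "Blomberg's K" else
    "Goodall's F"
  cat(sprintf("%s = %.4g, permutation p = %.4g (%s, %d %s)%s\n",
              lab, x$statistic, x$p_value, x$method, x$n_permutations,
              if (x$method == "exhaustive") "splits" else "permutations",
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise Goodall's F battery with Bonferroni control
#'
#' Runs [goodall_f()] plus [permutation_test()] for every unordered pair of
#' groups, each pair superimposed in isolation (mirroring the two-group
#' tools of the morphometrics literature) unless `global = TRUE`, in which
#' case a single joint superimposition of all specimens is sliced. The
#' Bonferroni-corrected level is `alpha / choose(n_groups, 2)`, counting
#' all pairs of the declared groups; singleton groups are skipped with a
#' warning (their pairs stay `NA`).
#'
#' @param coords k x 2 x n coordinate array.
#' @param grouping length-n group label vector.
#' @param n_permutations permutations per pair (default 1999).
#' @param seed integer; pair tests use `seed`, `seed + 1`, ... so the whole
#'   battery is reproducible.
#' @param alpha familywise base level (default 0.05).
#' @param slide slide semi-landmarks during each pairwise superimposition
#'   (default `FALSE`).
#' @param global use one global superimposition instead of per-pair
#'   (default `FALSE`).
#' @return object of class `pairwise_matrix`: `groups`, `F` and `p`
#'   (symmetric matrices), `significant` (logical matrix at
#'   `alpha_corrected`), `alpha_corrected`, `n_per_group`, `tests` (list of
#'   `shape_test`).
#' @export
pairwise_shape_tests <- function(coords, grouping, n_permutations = 1999,
                                 seed = NULL, alpha = 0.05, slide = FALSE,
                                 global = FALSE) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- table(grouping)[groups]
  n_pairs <- choose(length(groups), 2)
  alpha_corrected <- alpha / n_pairs
  Fm <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  Pm <- Fm
  Sm <- matrix(NA, length(groups), length(groups),
               dimnames = list(groups, groups))
  tests <- list()
  pair_i <- 0L
  Zg <- if (global) .aligned_cx(.maybe_slide(coords, slide)) else NULL
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    pair_i <- pair_i + 1L
    gi <- groups[i]; gj <- groups[j]
    if (sizes[gi] < 2 || sizes[gj] < 2) {
      warning("pair ", gi, " vs ", gj,
              " skipped: group with fewer than 2 specimens")
      next
    }
    sel <- grouping %in% c(gi, gj)
    pair_seed <- if (is.null(seed)) NULL else seed + pair_i
    if (global) {
      tst <- .permutation_test_cx(Zg[sel, , drop = FALSE],
                                  grouping[sel] == gi, n_permutations,
                                  pair_seed, alpha_corrected)
    } else {
      sub <- coords[, , sel, drop = FALSE]
      if (slide) sub <- .maybe_slide(sub, TRUE)
      tst <- permutation_test(sub, grouping[sel],
                              n_permutations = n_permutations,
                              seed = pair_seed, alpha = alpha_corrected)
    }
    Fm[gi, gj] <- Fm[gj, gi] <- tst$statistic
    Pm[gi, gj] <- Pm[gj, gi] <- tst$p_value
    Sm[gi, gj] <- Sm[gj, gi] <- tst$p_value < alpha_corrected
    tests[[paste(gi, gj, sep = " vs ")]] <- tst
  }
  structure(list(groups = groups, F = Fm, p = Pm, significant = Sm,
                 alpha_corrected = alpha_corrected,
                 n_per_group = as.integer(sizes), tests = tests),
            class = "pairwise_matrix")
}

.maybe_slide <- function(coords, slide) {
  if (!slide) return(coords)
  g <- gpa(coords, slide = TRUE)
  g$aligned
}

# permutation test on an already-aligned complex matrix (global mode)
.permutation_test_cx <- function(Z, is_a, n_permutations, seed, alpha) {
  ia <- which(is_a)
  obs <- .fast_goodall(Z, ia)
  n <- nrow(Z); na <- length(ia)
  if (choose(n, na) <= 10000) {
    splits <- combn(n, na)
    fs <- apply(splits, 2, function(idx) .fast_goodall(Z, idx))
    p <- mean(fs >= obs - 1e-12)
    n_used <- ncol(splits); method <- "exhaustive"
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations))
      if (.fast_goodall(Z, sample.int(n, na)) >= obs - 1e-12) ge <- ge + 1L
    p <- (1 + ge) / (1 + n_permutations)
    n_used <- n_permutations; method <- "random"
  }
  structure(list(statistic = obs, p_value = p, n_per_group = c(na, n - na),
                 n_permutations = n_used, seed = seed,
                 significant = p < alpha, alpha = alpha, method = method),
            class = "shape_test")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("Pairwise Goodall's F battery:", length(x$groups), "groups,",
      sum(!is.na(x$F[lower.tri(x$F)])), "tested pairs\n")
  cat("  Bonferroni-corrected alpha:",
      format(x$alpha_corrected, digits = 3), "\n")
  if (any(x$significant, na.rm = TRUE))
    cat("  significant pairs:",
        paste(names(x$tests)[vapply(x$tests, function(t)
          isTRUE(t$significant), logical(1))], collapse = "; "), "\n")
  invisible(x)
}

# exact two-sided rank-sum p by enumeration (tie-free small samples)
.exact_ranksum_p <- function(xi, xj) {
  pooled <- c(xi, xj)
  n <- length(pooled); ni <- length(xi)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(ni)]) - ni * (n + 1) / 2)
  splits <- combn(n, ni)
  stat <- abs(colSums(matrix(r[splits], nrow = ni)) - ni * (n + 1) / 2)
  mean(stat >= obs - 1e-9)
}

#' Kruskal-Wallis test with pairwise multiple comparisons
#'
#' Overall rank test (tie-corrected H via [stats::kruskal.test()]) plus the
#' classic multiple-comparison procedure on mean ranks: pair (i, j) is
#' called significant when
#' `|Rbar_i - Rbar_j| > z_{1 - alpha'/2} * sqrt(N(N+1)/12 * (1/n_i + 1/n_j))`
#' with `alpha' = alpha / n_pairs` shared Bonferroni-style across all
#' pairs. A per-pair p-value is also reported: the exact two-sided rank-sum
#' enumeration for small tie-free pairs, otherwise the normal
#' approximation to the mean-rank difference.
#'
#' @param values numeric vector of per-specimen measurements (e.g. angle
#'   of curvature in degrees).
#' @param grouping group label vector, >= 2 groups with >= 2 observations
#'   each.
#' @param alpha familywise base level (default 0.05).
#' @param exact_limit enumerate the exact pair p when the pair's split
#'   count is at most this and the pair is tie-free (default 10000).
#' @return object of class `kw_mc`: `H`, `df`, `p_overall`, `groups`,
#'   `mean_ranks`, `diff` / `critical` / `p` / `significant` (pairwise
#'   matrices), `alpha_corrected`.
#' @export
kruskal_wallis_mc <- function(values, grouping, alpha = 0.05,
                              exact_limit = 10000) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(table(grouping)[groups] < 2))
    stop("every group needs at least 2 observations")
  if (var(values) == 0) {
    # all observations identical: every rank is tied, H is 0 by convention
    kt <- list(statistic = c(H = 0), parameter = c(df = length(groups) -
                                                     1), p.value = 1)
  } else {
    kt <- kruskal.test(values, factor(grouping, levels = groups))
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, grouping, mean)[groups]
  rbar <- stats::setNames(as.numeric(rbar), groups)
  ns <- table(grouping)[groups]
  npairs <- choose(length(groups), 2)
  alpha_c <- alpha / npairs
  zc <- qnorm(1 - alpha_c / 2)
  Dm <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  Cm <- Dm; Pm <- Dm
  Sm <- matrix(NA, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    gi <- groups[i]; gj <- groups[j]
    d <- abs(rbar[gi] - rbar[gj])
    se <- sqrt(N * (N + 1) / 12 * (1 / ns[gi] + 1 / ns[gj]))
    crit <- zc * se
    xi <- values[grouping == gi]; xj <- values[grouping == gj]
    tie_free <- !anyDuplicated(c(xi, xj))
    p <- if (tie_free &&
             choose(length(xi) + length(xj), length(xi)) <= exact_limit)
      .exact_ranksum_p(xi, xj)
    else
      2 * pnorm(-d / se)
    Dm[gi, gj] <- Dm[gj, gi] <- d
    Cm[gi, gj] <- Cm[gj, gi] <- crit
    Pm[gi, gj] <- Pm[gj, gi] <- p
    Sm[gi, gj] <- Sm[gj, gi] <- d > crit
  }
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_overall = kt$p.value, groups = groups,
                 mean_ranks = rbar, diff = Dm, critical = Cm, p = Pm,
                 significant = Sm, alpha_corrected = alpha_c),
            class = "kw_mc")
}

#' @export
print.kw_mc <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_overall))
  cat("  Bonferroni-corrected pairwise alpha:",
      format(x$alpha_corrected, digits = 3), "\n")
  invisible(x)
}

#' Blomberg's K phylogenetic signal for a continuous trait
#'
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, where MSE0 is the mean squared
#' deviation of tip values from the phylogenetically (GLS) weighted mean,
#' MSE the generalized least-squares error under the tree's tip covariance
#' V, and the Brownian-motion expectation is
#' `(tr(V) - n / sum(V^-1)) / (n - 1)`. K is about 1 when the trait
#' evolved by Brownian motion on the tree, below 1 when relatives resemble
#' each other less than Brownian motion predicts. The p-value comes from
#' tip-shuffling permutations of the trait (K recomputed per shuffle).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param trait named numeric vector covering every tip.
#' @param n_permutations tip shuffles for the p-value (default 999; 0
#'   skips the test and returns `p_value = NA`).
#' @param seed integer seed for the shuffles.
#' @param alpha level for the `significant` flag (default 0.05).
#' @return object of class `shape_test` with `statistic` = K.
#' @export
blomberg_k <- function(tree, trait, n_permutations = 999, seed = NULL,
                       alpha = 0.05) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait must have one value per tip")
    names(trait) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait missing for some tips")
  x <- trait[tree$tip.label]
  if (var(x) == 0) stop("trait has zero variance")
  V <- ape::vcv(tree)
  Vinv <- solve(V)
  n <- length(x)
  expected <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
  k_of <- function(x) {
    a <- sum(Vinv %*% x) / sum(Vinv)
    d <- x - a
    mse0 <- sum(d^2) / (n - 1)
    mse <- as.numeric(t(d) %*% Vinv %*% d) / (n - 1)
    (mse0 / mse) / expected
  }
  obs <- k_of(x)
  p <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations))
      if (k_of(sample(x)) >= obs - 1e-12) ge <- ge + 1L
    p <- (1 + ge) / (1 + n_permutations)
  }
  structure(list(statistic = obs, p_value = p, n_per_group = n,
                 n_permutations = n_permutations, seed = seed,
                 significant = isTRUE(p < alpha), alpha = alpha,
                 method = "Blomberg K, tip permutation"),
            class = "shape_test")
}

#' Per-axis Blomberg's K for a matrix of warp scores
#'
#' Applies [blomberg_k()] to each column (relative warp axis) of a score
#' matrix independently and reports a variance-weighted summary K with a
#' joint tip-permutation p-value (the same shuffle applied to every axis).
#' This per-axis reading is one plausible treatment of matrix-valued
#' traits; a single multivariate K is deliberately not computed.
#'
#' @param tree an [ape::phylo] tree.
#' @param scores n_tips x m score matrix, rownames matching tip labels.
#' @param n_permutations joint tip shuffles (default 999).
#' @param seed integer seed.
#' @param alpha level for significance flags (default 0.05).
#' @return object of class `multi_k`: `per_axis` (data.frame with axis, K,
#'   p), `summary_k` (variance-weighted mean K), `summary_p`, `weights`.
#' @export
multivariate_k <- function(tree, scores, n_permutations = 999,
                           seed = NULL, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    if (nrow(scores) != length(tree$tip.label))
      stop("scores must have one row per tip")
    rownames(scores) <- tree$tip.label
  }
  vars <- apply(scores, 2, var)
  keep <- which(vars > 1e-12)
  if (length(keep) < ncol(scores))
    warning("skipping ", ncol(scores) - length(keep),
            " zero-variance axis/axes")
  scores <- scores[, keep, drop = FALSE]
  vars <- vars[keep]
  w <- vars / sum(vars)
  per <- lapply(seq_len(ncol(scores)), function(j)
    blomberg_k(tree, scores[, j], n_permutations = n_permutations,
               seed = if (is.null(seed)) NULL else seed + j,
               alpha = alpha))
  ks <- vapply(per, `[[`, numeric(1), "statistic")
  ps <- vapply(per, `[[`, numeric(1), "p_value")
  summary_k <- sum(w * ks)
  # joint permutation: same tip shuffle on all axes
  summary_p <- NA_real_
  if (n_permutations > 0) {
    V <- ape::vcv(tree); Vinv <- solve(V)
    n <- nrow(scores)
    expected <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
    X <- scores[tree$tip.label, , drop = FALSE]
    wk_of <- function(X) {
      ks <- vapply(seq_len(ncol(X)), function(j) {
        x <- X[, j]
        a <- sum(Vinv %*% x) / sum(Vinv)
        d <- x - a
        (sum(d^2) / as.numeric(t(d) %*% Vinv %*% d)) / expected
      }, numeric(1))
      sum(w * ks)
    }
    obs <- wk_of(X)
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations))
      if (wk_of(X[sample.int(n), , drop = FALSE]) >= obs - 1e-12)
        ge <- ge + 1L
    summary_p <- (1 + ge) / (1 + n_permutations)
  }
  structure(list(per_axis = data.frame(axis = seq_along(ks), K = ks,
                                       p = ps, weight = w),
                 summary_k = summary_k, summary_p = summary_p,
                 weights = w),
            class = "multi_k")
}

#' @export
print.multi_k <- function(x, ...) {
  cat("Per-axis Blomberg's K on", nrow(x$per_axis), "axes\n")
  cat(sprintf("  variance-weighted summary K = %.4g (p = %.4g)\n",
              x$summary_k, x$summary_p))
  invisible(x)
}

#' Bonferroni-corrected pairwise significance level
#'
#' @param n_groups number of groups in a pairwise battery.
#' @param alpha familywise base level (default 0.05).
#' @return `alpha / choose(n_groups, 2)`.
#' @export
bonferroni_alpha <- function(n_groups, alpha = 0.05) {
  if (n_groups < 2) stop("need at least 2 groups")
  alpha / choose(n_groups, 2)
}
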