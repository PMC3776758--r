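# Shared fixture builders (all generated in code; no stored data).

# m points on a circle of radius r, clockwise, starting at angle 0
circle_points <- function(m, r = 1) {
  th <- 2 * pi * (seq_len(m) - 1) / m
  cbind(r * cos(-th), r * sin(-th))
}

# m points on an axis-aligned ellipse, clockwise
ellipse_points <- function(m, a = 2, b = 1) {
  th <- 2 * pi * (seq_len(m) - 1) / m
  cbind(a * cos(-th), b * sin(-th))
}

# random smooth-ish closed k-point outline (radial perturbation of circle)
random_outline <- function(k, wobble = 0.15) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  r <- 1 + wobble * (cos(th * sample(1:3, 1) + runif(1, 0, 2 * pi)) +
                       0.5 * rnorm(1) * sin(2 * th))
  cbind(r * cos(-th), r * sin(-th))
}

# apply a random similarity transform (rotation + scale + translation)
random_similarity <- function(pts) {
  th <- runif(1, 0, 2 * pi)
  sc <- runif(1, 0.3, 3)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sc * pts %*% R + matrix(runif(2, -10, 10), nrow(pts), 2, byrow = TRUE)
}

# stack matrices into a k x 2 x n array
shape_array <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && !is.matrix(lst[[1]]))
    lst <- lst[[1]]
  arr <- array(NA_real_, c(nrow(lst[[1]]), 2, length(lst)))
  for (i in seq_along(lst)) arr[, , i] <- lst[[i]]
  arr
}

# noisy copies of a mean shape
noisy_group <- function(mean_shape, n, sd) {
  shape_array(lapply(seq_len(n), function(i)
    mean_shape + matrix(rnorm(2 * nrow(mean_shape), sd = sd), ncol = 2)))
}

# arc-length position of each query point along a dense closed polyline;
# used as an oracle independent of resample_outline's internals
arc_positions <- function(poly, query) {
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  vapply(seq_len(nrow(query)), function(i) {
    p <- query[i, ]
    best <- Inf; pos <- NA_real_
    for (j in seq_len(nrow(closed) - 1)) {
      a <- closed[j, ]; b <- closed[j + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(1, max(0, t))
      d <- sum((a + t * ab - p)^2)
      if (d < best) { best <- d; pos <- cum[j] + t * seg[j] }
    }
    pos
  }, numeric(1))
}
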