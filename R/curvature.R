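# Angle of curvature of the radius: the three-point metric relating the
# plane of the radial head to the long axis of the shaft. 90 degrees reads
# as a straight radius (unable to cross the ulna); departures from 90
# indicate a curved radius able to cross the ulna. The vertex is the
# proximal lateral radial-head point; the two rays run to the lateral
# distal end of the shaft and across the radial head to the medial
# surface.

#' Three-point angle of curvature
#'
#' Interior angle, in degrees, at `p_vertex` between the rays to
#' `p_distal` and `p_head_medial`. Invariant under rotation, translation,
#' uniform scaling and mirroring of the digitized points.
#'
#' @param p_distal,p_vertex,p_head_medial length-2 numeric vectors (or
#'   n x 2 matrices for vectorized use): the distal shaft point, the
#'   proximal lateral radial-head point (the vertex), and the medial
#'   radial-head point.
#' @return angle in degrees, in (0, 180]; vector for matrix input.
#' @export
angle_of_curvature <- function(p_distal, p_vertex, p_head_medial) {
  to_mat <- function(p) if (is.matrix(p)) p else matrix(p, 1, 2)
  a <- to_mat(p_distal); v <- to_mat(p_vertex); b <- to_mat(p_head_medial)
  u <- a - v; w <- b - v
  nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
  if (any(nu < 1e-12) || any(nw < 1e-12))
    stop("coincident points: angle undefined")
  cosang <- pmin(1, pmax(-1, rowSums(u * w) / (nu * nw)))
  ang <- acos(cosang) * 180 / pi
  if (length(ang) == 1) as.numeric(ang) else ang
}

#' Classify an angle of curvature as straight or curved
#'
#' A radius is called straight when its angle of curvature lies within
#' `tolerance_deg` of 90 degrees (closed interval), curved otherwise. The
#' tolerance is a reported parameter of the classification, not a hidden
#' constant; the default 0 treats only exactly 90 degrees as straight.
#'
#' @param angle_deg angle(s) in degrees, in (0, 180].
#' @param tolerance_deg half-width of the straight band (default 0).
#' @return character vector, `"straight"` or `"curved"`.
#' @export
classify_curvature <- function(angle_deg, tolerance_deg = 0) {
  if (any(angle_deg <= 0 | angle_deg > 180))
    stop("angles must lie in (0, 180]")
  ifelse(abs(angle_deg - 90) <= tolerance_deg, "straight", "curved")
}

#' Compute an angle table from digitized three-point records
#'
#' @param records data.frame with columns `specimen_id`, `distal_x`,
#'   `distal_y`, `vertex_x`, `vertex_y`, `medial_x`, `medial_y`.
#' @return the input with an `angle_deg` column appended.
#' @export
angle_table <- function(records) {
  need <- c("specimen_id", "distal_x", "distal_y", "vertex_x", "vertex_y",
            "medial_x", "medial_y")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  records$angle_deg <- angle_of_curvature(
    as.matrix(records[, c("distal_x", "distal_y")]),
    as.matrix(records[, c("vertex_x", "vertex_y")]),
    as.matrix(records[, c("medial_x", "medial_y")]))
  records
}
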