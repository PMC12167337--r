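#' Measure fracture angulation against the growth-plate perpendicular
#'
#' The clinical protocol measures the dislocation of the distal fragment
#' as the angle between the fragment (or diaphysis) axis and the line
#' perpendicular to the growth plate. A bone with the axis exactly
#' perpendicular to its growth plate therefore reads 0 degrees.
#'
#' @param growth_plate 2 x 2 matrix: two points (mm) on the growth plate.
#' @param distal_axis 2 x 2 matrix: two points (mm) on the fragment or
#'   diaphysis axis.
#' @param signed If `TRUE`, return the signed angle (positive when the
#'   axis is rotated from the plate perpendicular towards positive theta
#'   in the y-down frame), in `(-90, 90]`. Default is the unsigned acute
#'   angle in `[0, 90]`, as angulation magnitudes are reported clinically.
#' @return Angle in degrees.
#' @export
measure_angulation <- function(growth_plate, distal_axis, signed = FALSE) {
  g <- .segment_direction(growth_plate, "growth plate")
  a <- .segment_direction(distal_axis, "distal axis")
  perp <- c(-g[2], g[1]) # 90 deg rotation of the plate direction
  ang <- atan2(perp[1] * a[2] - perp[2] * a[1], sum(perp * a)) * 180 / pi
  # fold to the acute angle between undirected lines
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  if (signed) ang else abs(ang)
}

.segment_direction <- function(seg, what) {
  seg <- as.matrix(seg)
  if (!all(dim(seg) == c(2, 2))) stop(what, " must be a 2 x 2 matrix of endpoints")
  v <- seg[2, ] - seg[1, ]
  n <- sqrt(sum(v^2))
  if (n == 0) stop(what, " segment has zero length")
  v / n
}

#' Build angulation inputs from landmarks and a growth-plate direction
#'
#' The distal axis is the diaphysis direction `L_d0 -> L_d1`; the growth
#' plate passes through the physis landmark `L_p` with the supplied
#' direction (measured manually or taken from phantom ground truth).
#'
#' @param lm A [landmark_set()].
#' @param plate_direction Length-2 nonzero vector: growth-plate direction.
#' @return A list with elements `growth_plate` and `distal_axis`, each a
#'   2 x 2 matrix, suitable for [measure_angulation()].
#' @export
axes_from_landmarks <- function(lm, plate_direction) {
  stopifnot(inherits(lm, "landmark_set"))
  pd <- as.numeric(plate_direction)
  if (length(pd) != 2 || sum(pd^2) == 0) stop("plate_direction must be a nonzero 2-vector")
  list(growth_plate = rbind(lm$L_p, lm$L_p + pd),
       distal_axis  = rbind(lm$L_d0, lm$L_d1))
}
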