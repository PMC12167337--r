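#' Rigid 2D transform with optional pre-flip
#'
#' Represents the mapping from moving-image to fixed-image coordinates:
#' an optional horizontal mirror about the x = 0 axis (applied first),
#' followed by a rotation and a translation. All coordinates are physical
#' millimetres in the image frame: origin at the top-left corner, x
#' increasing rightward, y increasing downward. `theta` is in radians and
#' rotates `(1, 0)` towards `(0, 1)` for positive angles (counter-clockwise
#' in the y-down frame).
#'
#' @param theta Rotation angle, radians.
#' @param tx,ty Translation, mm.
#' @param pre_flip If `TRUE`, the point is mirrored (`x -> -x`) before the
#'   rigid part. Used when the moving view is acquired from the opposite
#'   scan orientation (e.g. the palmar view aligned to a dorsal view).
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(theta = pi / 2)
#' apply_point(t, c(1, 0)) # (0, 1)
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0, pre_flip = FALSE) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty),
            is.logical(pre_flip), length(pre_flip) == 1L)
  structure(list(theta = theta, tx = tx, ty = ty, pre_flip = pre_flip),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: theta = %.4f deg, t = (%.4f, %.4f) mm, pre_flip = %s\n",
              x$theta * 180 / pi, x$tx, x$ty, x$pre_flip))
  invisible(x)
}

#' Homogeneous 3x3 matrix of a rigid transform
#'
#' The flip (if any) acts about the x = 0 axis before rotation and
#' translation, so the linear part is `R %*% F` with
#' `F = diag(c(-1, 1))` when `pre_flip` is set.
#'
#' @param t A [rigid_transform()].
#' @return A 3x3 numeric matrix acting on homogeneous column vectors
#'   `(x, y, 1)`.
#' @export
to_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  cs <- cos(t$theta); sn <- sin(t$theta)
  R <- matrix(c(cs, sn, -sn, cs), 2, 2) # column-major: R %*% (1,0) = (cs, sn)
  L <- if (t$pre_flip) R %*% diag(c(-1, 1)) else R
  rbind(cbind(L, c(t$tx, t$ty)), c(0, 0, 1))
}

#' Recover transform parameters from a homogeneous matrix
#'
#' Inverse of [to_matrix()]. The linear part must be orthonormal with
#' determinant +1 (no flip) or -1 (flip about x = 0 folded into the
#' rotation).
#'
#' @param m A 3x3 homogeneous matrix.
#' @param tol Orthonormality tolerance.
#' @return A [rigid_transform()]; `theta` is the principal value in
#'   `(-pi, pi]`.
#' @export
matrix_to_transform <- function(m, tol = 1e-6) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  L <- m[1:2, 1:2]
  d <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  if (max(abs(crossprod(L) - diag(2))) > tol)
    stop("linear part is not orthonormal: not a rigid(+flip) transform")
  pre_flip <- d < 0
  R <- if (pre_flip) L %*% diag(c(-1, 1)) else L
  rigid_transform(theta = atan2(R[2, 1], R[1, 1]),
                  tx = m[1, 3], ty = m[2, 3], pre_flip = pre_flip)
}

#' Apply a rigid transform to points
#'
#' @param t A [rigid_transform()].
#' @param p A length-2 numeric vector or an n x 2 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_point <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- !is.matrix(p)
  pm <- if (vec) matrix(p, ncol = 2) else p
  stopifnot(ncol(pm) == 2)
  if (t$pre_flip) pm[, 1] <- -pm[, 1]
  cs <- cos(t$theta); sn <- sin(t$theta)
  out <- cbind(cs * pm[, 1] - sn * pm[, 2] + t$tx,
               sn * pm[, 1] + cs * pm[, 2] + t$ty)
  if (vec) c(out) else out
}

#' Apply only the linear part of a rigid transform to displacement vectors
#'
#' Translation does not act on displacements; the flip (if any) and the
#' rotation do. The Euclidean norm is preserved.
#'
#' @inheritParams apply_point
#' @param v A length-2 displacement or an n x 2 matrix of displacements.
#' @export
apply_vector <- function(t, v) {
  t0 <- rigid_transform(t$theta, 0, 0, t$pre_flip)
  apply_point(t0, v)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`compose(a, b)(p) == a(b(p))`). At most one operand may carry a
#' pre-flip: the flip is defined to act first, so a flip in the outer
#' transform cannot be expressed in the flip-then-rigid normal form
#' unless the inner transform is flip-free.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose <- function(a, b) {
  if (a$pre_flip && b$pre_flip)
    stop("cannot compose two pre-flip transforms in flip-then-rigid form")
  matrix_to_transform(to_matrix(a) %*% to_matrix(b))
}

#' Invert a rigid transform
#'
#' Only flip-free transforms invert within the flip-then-rigid normal form;
#' for a flipped transform the inverse applies the rigid inverse first and
#' the flip last, which this parameterization cannot express.
#'
#' @param t A flip-free [rigid_transform()].
#' @export
invert <- function(t) {
  if (t$pre_flip)
    stop("inverse of a pre-flip transform is not representable in flip-then-rigid form")
  matrix_to_transform(solve(to_matrix(t)))
}

#' Serialize / deserialize a transform as JSON
#'
#' The JSON object has keys `theta_deg`, `tx_mm`, `ty_mm`, `pre_flip` and
#' `matrix` (3x3, row-major).
#'
#' @param t A [rigid_transform()].
#' @param path File path; for `transform_to_json` with `path = NULL` the
#'   JSON string is returned instead of written.
#' @return `transform_to_json`: the JSON string (invisibly when written to
#'   a file). `transform_from_json`: a [rigid_transform()].
#' @export
transform_to_json <- function(t, path = NULL) {
  m <- to_matrix(t)
  obj <- list(theta_deg = t$theta * 180 / pi, tx_mm = t$tx, ty_mm = t$ty,
              pre_flip = t$pre_flip,
              matrix = lapply(1:3, function(i) as.numeric(m[i, ])))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(12), pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (k in c("theta_deg", "tx_mm", "ty_mm", "pre_flip"))
    if (is.null(obj[[k]])) stop("transform JSON missing key: ", k)
  rigid_transform(theta = obj$theta_deg * pi / 180, tx = obj$tx_mm,
                  ty = obj$ty_mm, pre_flip = isTRUE(obj$pre_flip))
}

#' Ordered 2D polyline in physical coordinates
#'
#' @param points An n x 2 matrix (mm), n >= 2, consecutive points distinct.
#' @param closed Whether the last point connects back to the first.
#' @return An object of class `polyline`.
#' @export
polyline <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2, all(is.finite(points)))
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0)) stop("consecutive polyline points must be distinct")
  structure(list(points = points, closed = isTRUE(closed)), class = "polyline")
}

#' Arc length of a polyline (mm)
#' @param poly A [polyline()].
#' @export
arc_length <- function(poly) {
  pts <- poly$points
  if (poly$closed) pts <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Transform every vertex of a polyline
#' @param poly A [polyline()].
#' @param t A [rigid_transform()].
#' @export
transform_polyline <- function(poly, t) {
  polyline(apply_point(t, poly$points), closed = poly$closed)
}
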