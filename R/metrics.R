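#' Directed Hausdorff distance between two point sets
#'
#' `max over a in A of min over b in B of |a - b|`, in mm. Asymmetric in
#' general: `directed_hausdorff(A, B) != directed_hausdorff(B, A)`.
#'
#' @param A,B n x 2 numeric matrices of points (mm); non-empty.
#' @return Distance in mm.
#' @export
directed_hausdorff <- function(A, B) {
  d <- .pairwise_dist(A, B)
  max(apply(d, 1, min))
}

#' Symmetric Chamfer distance between two point sets
#'
#' Half the sum of the two mean nearest-neighbour distances:
#' `0.5 * (mean_a min_b |a-b| + mean_b min_a |a-b|)`, in mm. Several
#' Chamfer variants exist in the literature (sum vs mean, squared vs
#' linear); this linear mean-of-means form is on the same mm scale as the
#' Hausdorff distance. Alternatives are available through `variant`.
#'
#' @param A,B n x 2 numeric matrices of points (mm); non-empty.
#' @param variant `"mean"` (default, symmetric mean of linear closest
#'   distances), `"sum"` (sum instead of mean in each direction) or
#'   `"squared"` (mean of squared closest distances).
#' @return Distance (mm, or mm^2 for `"squared"`).
#' @export
chamfer <- function(A, B, variant = c("mean", "sum", "squared")) {
  variant <- match.arg(variant)
  d <- .pairwise_dist(A, B)
  ab <- apply(d, 1, min); ba <- apply(d, 2, min)
  switch(variant,
         mean    = 0.5 * (mean(ab) + mean(ba)),
         sum     = 0.5 * (sum(ab) + sum(ba)),
         squared = 0.5 * (mean(ab^2) + mean(ba^2)))
}

.pairwise_dist <- function(A, B) {
  A <- .as_pointset(A); B <- .as_pointset(B)
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

.as_pointset <- function(x) {
  if (inherits(x, "polyline")) x <- x$points
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) != 2) stop("point set must be a non-empty n x 2 matrix")
  x
}

#' Resample a polyline to a point set at fixed arc-length step
#'
#' Points are placed every `step` mm along the curve, endpoints included
#' (the final interval may be shorter than `step`).
#'
#' @param poly A [polyline()].
#' @param step Sampling step, mm (> 0).
#' @return An n x 2 matrix of points (mm).
#' @export
polyline_to_pointset <- function(poly, step = 0.5) {
  stopifnot(step > 0)
  pts <- poly$points
  if (poly$closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- unique(c(seq(0, total, by = step), total))
  interp_along(pts, s, at)
}

# linear interpolation of polyline vertices pts (cumulative arc s) at
# arc positions `at`
interp_along <- function(pts, s, at) {
  x <- stats::approx(s, pts[, 1], xout = at, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2], xout = at, ties = "ordered")$y
  cbind(x, y)
}
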