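#' Binary bone-boundary mask with physical pixel spacing
#'
#' @param pixels Logical or numeric matrix; nonzero entries are foreground.
#'   Rows run down the image (y), columns run right (x).
#' @param spacing Isotropic pixel spacing, mm per pixel (> 0).
#' @return An object of class `boundary_mask`.
#' @export
boundary_mask <- function(pixels, spacing) {
  stopifnot(is.matrix(pixels), length(spacing) == 1L, is.finite(spacing), spacing > 0)
  px <- pixels != 0
  if (!any(px)) stop("no boundary: mask has no foreground pixels")
  structure(list(pixels = px, spacing = spacing), class = "boundary_mask")
}

#' Read a binary mask from a PNG/TIFF file
#'
#' Any nonzero pixel (first channel, for multi-channel files) is foreground.
#' Spacing is taken from the `spacing_mm` argument or, if `NULL`, from a
#' sidecar JSON file `<path>.json` with key `spacing_mm`.
#'
#' @param path PNG or TIFF file.
#' @param spacing_mm mm per pixel; `NULL` to read the sidecar file.
#' @return A [boundary_mask()].
#' @export
read_mask <- function(path, spacing_mm = NULL) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  if (is.null(spacing_mm)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("spacing not given and sidecar file not found: ", sidecar)
    spacing_mm <- jsonlite::fromJSON(sidecar)$spacing_mm
    if (is.null(spacing_mm)) stop("sidecar file lacks key 'spacing_mm': ", sidecar)
  }
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required for TIFF input")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  boundary_mask(arr, spacing_mm)
}

#' Write a binary mask as PNG
#' @param mask A [boundary_mask()].
#' @param path Output PNG path; a sidecar `<path>.json` with the spacing is
#'   written alongside.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$pixels * 1, path)
  writeLines(as.character(jsonlite::toJSON(list(spacing_mm = mask$spacing),
                                           auto_unbox = TRUE)),
             paste0(path, ".json"))
  invisible(path)
}

# pixel (row, col), 1-based -> physical mm with pixel (1,1) centred at (0,0)
.px_to_mm <- function(rc, spacing) cbind((rc[, 2] - 1) * spacing, (rc[, 1] - 1) * spacing)

#' Reduce a boundary mask to an ordered centerline polyline
#'
#' The largest 8-connected foreground component is thinned to a
#' single-pixel-wide skeleton (Zhang-Suen), short spurs are pruned, and the
#' path between the two remaining endpoints is ordered starting from the
#' leftmost endpoint. Pixel indices are converted to mm using the mask
#' spacing.
#'
#' @param mask A [boundary_mask()].
#' @param prune_mm Spur branches shorter than this are removed before the
#'   two-endpoint topology check (default 2 mm).
#' @return A [polyline()] in mm.
#' @export
mask_to_polyline <- function(mask, prune_mm = 2) {
  stopifnot(inherits(mask, "boundary_mask"))
  px <- .largest_component(mask$pixels)
  sk <- .thin_zhang_suen(px)
  path <- .skeleton_path(sk, prune_px = prune_mm / mask$spacing)
  if (nrow(path) < 2) stop("no boundary: skeleton degenerate")
  pts <- .px_to_mm(path, mask$spacing)
  keep <- c(TRUE, rowSums(diff(pts)^2) > 0)
  polyline(pts[keep, , drop = FALSE])
}

.largest_component <- function(px) {
  lab <- EBImage::bwlabel(px)
  if (max(lab) == 0) stop("no boundary: mask has no foreground pixels")
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning on a logical matrix; vectorized over the raster.
.thin_zhang_suen <- function(px) {
  m <- px
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9, clockwise from north (row-1)
      p2 <- .shift_mat(m, 1, 0);  p3 <- .shift_mat(m, 1, -1)
      p4 <- .shift_mat(m, 0, -1); p5 <- .shift_mat(m, -1, -1)
      p6 <- .shift_mat(m, -1, 0); p7 <- .shift_mat(m, -1, 1)
      p8 <- .shift_mat(m, 0, 1);  p9 <- .shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Order skeleton pixels into a path: prune spurs < prune_px, require exactly
# two endpoints, then BFS shortest path from the leftmost endpoint.
.skeleton_path <- function(sk, prune_px) {
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) == 1) return(idx)
  nr <- nrow(sk)
  key <- function(rc) (rc[, 2] - 1) * nr + rc[, 1]
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]

  alive <- new.env(hash = TRUE, size = nrow(idx) * 2)
  for (i in seq_len(nrow(idx))) assign(as.character(key(idx[i, , drop = FALSE])), idx[i, ], envir = alive)
  neighbours <- function(rc) {
    out <- list()
    for (j in seq_len(nrow(offs))) {
      nb <- rc + c(offs$dr[j], offs$dc[j])
      if (exists(as.character((nb[2] - 1) * nr + nb[1]), envir = alive, inherits = FALSE))
        out[[length(out) + 1]] <- nb
    }
    out
  }
  degree <- function(rc) length(neighbours(rc))
  all_pts <- function() {
    ks <- ls(alive)
    t(vapply(ks, function(k) get(k, envir = alive), numeric(2)))
  }

  # iterative spur pruning
  repeat {
    pts <- all_pts()
    deg <- apply(pts, 1, degree)
    ends <- pts[deg == 1, , drop = FALSE]
    if (nrow(ends) <= 2) break
    removed_any <- FALSE
    for (i in seq_len(nrow(ends))) {
      rc <- ends[i, ]
      if (!exists(as.character((rc[2] - 1) * nr + rc[1]), envir = alive, inherits = FALSE)) next
      branch <- list(rc); prev <- NULL; cur <- rc; len <- 0
      repeat {
        nbs <- neighbours(cur)
        if (!is.null(prev)) nbs <- Filter(function(p) !all(p == prev), nbs)
        if (length(nbs) != 1 || length(neighbours(cur)) >= 3) break
        nxt <- nbs[[1]]
        len <- len + sqrt(sum((nxt - cur)^2))
        if (len >= prune_px) break
        if (length(neighbours(nxt)) >= 3) break # junction ahead: branch ends here
        branch[[length(branch) + 1]] <- nxt
        prev <- cur; cur <- nxt
      }
      last_nbs <- neighbours(cur)
      at_junction <- length(last_nbs) >= 3 ||
        (length(branch) > 0 && {
          tipnbs <- neighbours(branch[[length(branch)]])
          any(vapply(tipnbs, function(p) length(neighbours(p)) >= 3, logical(1)))
        })
      if (len < prune_px && at_junction) {
        for (b in branch) rm(list = as.character((b[2] - 1) * nr + b[1]), envir = alive)
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }

  pts <- all_pts()
  deg <- apply(pts, 1, degree)
  ends <- pts[deg == 1, , drop = FALSE]
  if (nrow(ends) != 2)
    stop("ambiguous boundary topology: skeleton has ", nrow(ends),
         " endpoints after pruning")
  # leftmost endpoint (smallest column; topmost on ties) starts the path
  ord <- order(ends[, 2], ends[, 1])
  start <- ends[ord[1], ]; goal <- ends[ord[2], ]

  # BFS shortest path over the pruned skeleton
  prevmap <- new.env(hash = TRUE)
  qk <- as.character((start[2] - 1) * nr + start[1])
  assign(qk, c(NA, NA), envir = prevmap)
  queue <- list(start); qi <- 1
  found <- FALSE
  while (qi <= length(queue)) {
    cur <- queue[[qi]]; qi <- qi + 1
    if (all(cur == goal)) { found <- TRUE; break }
    for (nb in neighbours(cur)) {
      k <- as.character((nb[2] - 1) * nr + nb[1])
      if (!exists(k, envir = prevmap, inherits = FALSE)) {
        assign(k, cur, envir = prevmap)
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  if (!found) stop("ambiguous boundary topology: endpoints not connected")
  path <- list(goal); cur <- goal
  repeat {
    prev <- get(as.character((cur[2] - 1) * nr + cur[1]), envir = prevmap)
    if (any(is.na(prev))) break
    path[[length(path) + 1]] <- prev
    cur <- prev
  }
  do.call(rbind, rev(path))
}

#' Landmark extraction configuration
#'
#' @param d0_arc_distance Arc distance (mm) from `L_d1` back along the
#'   boundary to place `L_d0`; clinically "approximately 2-3 cm", default 25.
#' @param min_diaphysis_length Sliding-window length (mm) used to detect the
#'   near-horizontal diaphysis run, default 15.
#' @param horizontal_tol Maximum absolute angle (degrees) of a window's
#'   least-squares direction to the x-axis for it to count as diaphysis,
#'   default 20.
#' @param d1_percentile `L_d1` is placed at this percentile of x within the
#'   longest diaphysis run (default 0.9), avoiding the metaphyseal flare at
#'   the extreme end.
#' @param physis_x_fraction The physis is searched within this leftmost
#'   fraction of the polyline's x-range, default 0.35.
#' @param physis_lambda Weight on `-x` in the lower-left score
#'   `y - lambda * x`, default 0.2 (ties broken towards "lower").
#' @param physis_side `"left"` (default) when the physis lies at the left of
#'   the scan, `"right"` for mirrored acquisitions: the polyline is mirrored
#'   internally and results mirrored back.
#' @param resample_step Internal resampling step (mm) for windowed direction
#'   estimates, default 0.25.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(d0_arc_distance = 25, min_diaphysis_length = 15,
                            horizontal_tol = 20, d1_percentile = 0.9,
                            physis_x_fraction = 0.35, physis_lambda = 0.2,
                            physis_side = c("left", "right"),
                            resample_step = 0.25) {
  stopifnot(d0_arc_distance > 0, min_diaphysis_length > 0, horizontal_tol > 0,
            d1_percentile > 0, d1_percentile <= 1,
            physis_x_fraction > 0, physis_x_fraction <= 1, resample_step > 0)
  structure(list(d0_arc_distance = d0_arc_distance,
                 min_diaphysis_length = min_diaphysis_length,
                 horizontal_tol = horizontal_tol,
                 d1_percentile = d1_percentile,
                 physis_x_fraction = physis_x_fraction,
                 physis_lambda = physis_lambda,
                 physis_side = match.arg(physis_side),
                 resample_step = resample_step),
            class = "landmark_config")
}

#' Anatomical landmark set (physis + two diaphysis points)
#'
#' @param L_p Physis point (mm), length-2.
#' @param L_d0,L_d1 Proximal / distal diaphysis points (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(L_p, L_d0, L_d1) {
  L_p <- as.numeric(L_p); L_d0 <- as.numeric(L_d0); L_d1 <- as.numeric(L_d1)
  stopifnot(length(L_p) == 2, length(L_d0) == 2, length(L_d1) == 2,
            all(is.finite(c(L_p, L_d0, L_d1))))
  if (sum((L_d0 - L_d1)^2) == 0) stop("diaphysis landmarks coincide")
  structure(list(L_p = L_p, L_d0 = L_d0, L_d1 = L_d1), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmarks (mm): L_p = (%.2f, %.2f)  L_d0 = (%.2f, %.2f)  L_d1 = (%.2f, %.2f)\n",
              x$L_p[1], x$L_p[2], x$L_d0[1], x$L_d0[2], x$L_d1[1], x$L_d1[2]))
  invisible(x)
}

#' Derive the three anatomical landmarks from a boundary polyline
#'
#' `L_d1` is found on the long near-horizontal diaphysis segment: windows of
#' `min_diaphysis_length` mm slide along the curve, windows whose
#' least-squares direction lies within `horizontal_tol` degrees of the
#' x-axis are marked, and `L_d1` sits at the `d1_percentile` of x within the
#' longest marked run. `L_d0` lies `d0_arc_distance` mm back along the curve
#' from `L_d1`. `L_p` (the physis) maximizes the lower-left score
#' `y - lambda * x` within the leftmost `physis_x_fraction` of the x-range.
#'
#' @param poly A [polyline()] of the bone boundary, mm.
#' @param cfg A [landmark_config()].
#' @return A [landmark_set()].
#' @export
extract_landmarks <- function(poly, cfg = landmark_config()) {
  stopifnot(inherits(poly, "polyline"), inherits(cfg, "landmark_config"))
  mirrored <- cfg$physis_side == "right"
  pts0 <- poly$points
  if (mirrored) pts0 <- cbind(-pts0[, 1], pts0[, 2])

  if (arc_length(poly) < cfg$d0_arc_distance)
    stop("insufficient boundary extent: arc length ",
         sprintf("%.1f", arc_length(poly)), " mm < d0 arc distance")

  pts <- polyline_to_pointset(polyline(pts0), step = cfg$resample_step)
  # orient the curve left-to-right so arc positions run physis -> diaphysis
  if (pts[1, 1] > pts[nrow(pts), 1]) pts <- pts[nrow(pts):1, , drop = FALSE]
  n <- nrow(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))

  # slide windows of min_diaphysis_length; mark vertices of near-horizontal ones
  W <- cfg$min_diaphysis_length
  tol <- cfg$horizontal_tol
  marked <- logical(n)
  jend <- pmin(n, findInterval(s + W, s) + 1L) # window [i, jend[i]] spans >= W mm (except near the tail)
  i <- 1L
  while (i <= n) {
    j <- jend[i]
    if (s[j] - s[i] < W) break
    w <- pts[i:j, , drop = FALSE]
    cc <- cov(w)
    ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    ang <- atan2(abs(ev[2]), abs(ev[1])) * 180 / pi
    if (ang <= tol) marked[i:j] <- TRUE
    i <- i + 1L
  }
  if (!any(marked)) stop("diaphysis not found: no near-horizontal run of ",
                         W, " mm within ", tol, " degrees")

  # longest contiguous marked run by arc length
  r <- rle(marked)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lens <- s[ends[runs]] - s[starts[runs]]
  best <- runs[which.max(lens)]
  ri <- starts[best]:ends[best]

  xr <- pts[ri, 1]
  q <- stats::quantile(xr, cfg$d1_percentile, names = FALSE, type = 7)
  k <- ri[which.min(abs(xr - q))]
  L_d1 <- pts[k, ]

  s0 <- s[k] - cfg$d0_arc_distance
  if (s0 < 0) stop("insufficient boundary extent: L_d1 lies closer than ",
                   cfg$d0_arc_distance, " mm to the curve start")
  L_d0 <- c(interp_along(pts, s, s0))

  xmin <- min(pts[, 1]); xmax <- max(pts[, 1])
  sel <- pts[, 1] <= xmin + cfg$physis_x_fraction * (xmax - xmin)
  score <- pts[sel, 2] - cfg$physis_lambda * pts[sel, 1]
  L_p <- pts[which(sel)[which.max(score)], ]

  if (mirrored) {
    L_p[1] <- -L_p[1]; L_d0[1] <- -L_d0[1]; L_d1[1] <- -L_d1[1]
  } else if (L_d0[1] >= L_d1[1]) {
    stop("diaphysis orientation inconsistent: L_d0 not left of L_d1")
  }
  landmark_set(L_p, L_d0, L_d1)
}

#' Read / write a landmark set as JSON
#'
#' Schema: `{"L_p": [x, y], "L_d0": [x, y], "L_d1": [x, y], "units": "mm"}`.
#'
#' @param path JSON file.
#' @param lm A [landmark_set()] (for writing).
#' @return `landmarks_from_file`: a [landmark_set()].
#' @export
landmarks_from_file <- function(path) {
  if (!file.exists(path)) stop("cannot read landmarks: no such file: ", path)
  obj <- jsonlite::fromJSON(path)
  for (k in c("L_p", "L_d0", "L_d1")) {
    if (is.null(obj[[k]])) stop("landmark JSON missing key: ", k)
    if (length(obj[[k]]) != 2 || !is.numeric(obj[[k]]))
      stop("landmark JSON key ", k, " must be a numeric [x, y] pair")
  }
  landmark_set(obj$L_p, obj$L_d0, obj$L_d1)
}

#' @rdname landmarks_from_file
#' @export
landmarks_to_file <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  obj <- list(L_p = lm$L_p, L_d0 = lm$L_d0, L_d1 = lm$L_d1, units = "mm")
  writeLines(as.character(jsonlite::toJSON(obj, digits = I(12), auto_unbox = TRUE)), path)
  invisible(path)
}
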