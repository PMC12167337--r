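#' Grayscale image with physical pixel spacing
#'
#' @param pixels Numeric matrix of intensities; rows run down (y), columns
#'   run right (x). Pixel `(1, 1)` is centred at physical `(0, 0)` mm plus
#'   the canvas origin.
#' @param spacing mm per pixel (> 0).
#' @param origin Physical position (mm) of the centre of pixel `(1, 1)`,
#'   default `c(0, 0)`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing, origin = c(0, 0)) {
  stopifnot(is.matrix(pixels), is.numeric(spacing) || is.integer(spacing),
            length(spacing) == 1L, spacing > 0, length(origin) == 2L)
  structure(list(pixels = pixels, spacing = spacing, origin = as.numeric(origin)),
            class = "gray_image")
}

#' Read a grayscale PNG/TIFF image
#' @param path Image file.
#' @param spacing_mm mm per pixel.
#' @export
read_gray <- function(path, spacing_mm) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required for TIFF input")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  gray_image(arr, spacing_mm)
}

# pixel-centre coordinate grids of an image, mm
.image_grid <- function(img) {
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  list(x = img$origin[1] + (seq_len(nc) - 1) * img$spacing,
       y = img$origin[2] + (seq_len(nr) - 1) * img$spacing)
}

#' Resample an image under a rigid transform onto a canvas
#'
#' Inverse-mapped resampling: each canvas pixel centre is pulled back
#' through the inverse transform and the source image is sampled there
#' (bilinear by default, nearest-neighbour for label masks). Pixels mapping
#' outside the source are 0.
#'
#' @param img A [gray_image()] (the moving image).
#' @param t A [rigid_transform()] mapping moving to canvas coordinates.
#' @param canvas A [gray_image()] or a list with `origin` (mm), `dim`
#'   (rows, cols) and `spacing`; `NULL` keeps the input geometry.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return A [gray_image()] on the canvas geometry.
#' @export
warp_image <- function(img, t, canvas = NULL,
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(img, "gray_image"), inherits(t, "rigid_transform"))
  if (is.null(canvas)) {
    cdim <- dim(img$pixels); corigin <- img$origin; cspacing <- img$spacing
  } else if (inherits(canvas, "gray_image")) {
    cdim <- dim(canvas$pixels); corigin <- canvas$origin; cspacing <- canvas$spacing
  } else {
    cdim <- canvas$dim; corigin <- canvas$origin; cspacing <- canvas$spacing
  }
  if (any(cdim < 1)) stop("degenerate canvas")

  Minv <- solve(to_matrix(t))
  gx <- corigin[1] + (seq_len(cdim[2]) - 1) * cspacing
  gy <- corigin[2] + (seq_len(cdim[1]) - 1) * cspacing
  X <- matrix(gx, cdim[1], cdim[2], byrow = TRUE)
  Y <- matrix(gy, cdim[1], cdim[2])
  sx <- Minv[1, 1] * X + Minv[1, 2] * Y + Minv[1, 3]
  sy <- Minv[2, 1] * X + Minv[2, 2] * Y + Minv[2, 3]
  # source pixel (fractional, 1-based)
  pc <- (sx - img$origin[1]) / img$spacing + 1
  pr <- (sy - img$origin[2]) / img$spacing + 1
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  out <- matrix(0, cdim[1], cdim[2])

  if (interpolation == "nearest") {
    rr <- round(pr); cc <- round(pc)
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[ok] <- img$pixels[cbind(rr[ok], cc[ok])]
  } else {
    # clamp so points landing exactly on the last row/column interpolate
    r0 <- pmin(floor(pr), nr - 1); c0 <- pmin(floor(pc), nc - 1)
    fr <- pr - r0; fc <- pc - c0
    ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc & r0 >= 1 & c0 >= 1
    if (any(ok)) {
      i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
      i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
      v <- img$pixels[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
           img$pixels[i01] * (1 - fr[ok]) * fc[ok] +
           img$pixels[i10] * fr[ok] * (1 - fc[ok]) +
           img$pixels[i11] * fr[ok] * fc[ok]
      out[ok] <- v
    }
  }
  gray_image(out, cspacing, corigin)
}

#' Fuse a fixed and a transformed moving view into a two-channel overlay
#'
#' The fixed image fills channel 1 and the moving image, resampled under
#' `t`, fills channel 2; rendered as red/green over black by
#' [write_fused_png()]. The canvas is the union bounding box of the fixed
#' extent and the transformed moving extent, plus a margin.
#'
#' @param fixed,moving [gray_image()] objects with equal spacing (set
#'   `resample = TRUE` to rescale the moving image otherwise).
#' @param t A [rigid_transform()] mapping moving to fixed coordinates.
#' @param margin_mm Canvas margin, default 5.
#' @param interpolation Passed to [warp_image()].
#' @param resample Permit resampling the moving image when spacings differ.
#' @return An object of class `fused_view`: list with `fixed`, `moving`
#'   (both [gray_image()] on the shared canvas), `spacing`, `origin`,
#'   `transform`.
#' @export
fuse <- function(fixed, moving, t, margin_mm = 5,
                 interpolation = c("bilinear", "nearest"), resample = FALSE) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(fixed, "gray_image"), inherits(moving, "gray_image"))
  if (abs(fixed$spacing - moving$spacing) > 1e-12) {
    if (!resample) stop("spacing mismatch: set resample = TRUE to rescale the moving image")
    moving <- .rescale_image(moving, fixed$spacing)
  }
  gf <- .image_grid(fixed)
  fx <- range(gf$x); fy <- range(gf$y)
  gm <- .image_grid(moving)
  corners <- as.matrix(expand.grid(x = range(gm$x), y = range(gm$y)))
  tc <- apply_point(t, corners)
  x0 <- min(fx[1], tc[, 1]) - margin_mm; x1 <- max(fx[2], tc[, 1]) + margin_mm
  y0 <- min(fy[1], tc[, 2]) - margin_mm; y1 <- max(fy[2], tc[, 2]) + margin_mm
  sp <- fixed$spacing
  cdim <- c(ceiling((y1 - y0) / sp) + 1, ceiling((x1 - x0) / sp) + 1)
  canvas <- list(dim = cdim, origin = c(x0, y0), spacing = sp)
  fx_ch <- warp_image(fixed, rigid_transform(), canvas, interpolation)
  mv_ch <- warp_image(moving, t, canvas, interpolation)
  structure(list(fixed = fx_ch, moving = mv_ch, spacing = sp,
                 origin = c(x0, y0), transform = t),
            class = "fused_view")
}

.rescale_image <- function(img, new_spacing) {
  scale <- img$spacing / new_spacing
  nd <- c(max(1, round(nrow(img$pixels) * scale)),
          max(1, round(ncol(img$pixels) * scale)))
  # pure rescale: identity geometry at the new spacing
  warp_image(img, rigid_transform(),
             list(dim = nd, origin = img$origin, spacing = new_spacing))
}

#' Write a fused view as an RGB PNG (fixed = red, moving = green)
#'
#' A JSON sidecar `<path>.json` records the canvas origin, spacing and the
#' transform.
#'
#' @param fv A [fuse()] result.
#' @param path Output PNG path.
#' @export
write_fused_png <- function(fv, path) {
  stopifnot(inherits(fv, "fused_view"))
  norm01 <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  arr <- array(0, c(dim(fv$fixed$pixels), 3))
  arr[, , 1] <- norm01(fv$fixed$pixels)
  arr[, , 2] <- norm01(fv$moving$pixels)
  png::writePNG(arr, path)
  meta <- list(origin_mm = fv$origin, spacing_mm = fv$spacing,
               transform = jsonlite::fromJSON(transform_to_json(fv$transform)))
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(12),
                                           pretty = TRUE)),
             paste0(path, ".json"))
  invisible(path)
}
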