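#' Synthetic phantom configuration
#'
#' Parameters of the paired dorsal/palmar bone-boundary phantom. Defaults
#' approximate a pediatric distal radius imaged in a ~6 cm longitudinal
#' window: a long near-horizontal diaphysis boundary, a steep metaphyseal
#' flare descending to the physis point at the lower left, a physis gap, and
#' a short separate epiphysis boundary beyond the gap. The palmar (moving)
#' cortex is the same curve offset by one bone width; the moving view is
#' optionally mirrored and always displaced by a seeded random rigid
#' perturbation, and all ground truth (landmarks, transform, angulation) is
#' recorded.
#'
#' @param diaphysis_length Diaphysis run length, mm (default 60).
#' @param bone_width Dorsal-palmar cortex separation, mm (default 10).
#' @param physis_gap Gap between metaphysis and epiphysis boundary, mm
#'   (default 3).
#' @param flare_height Drop of the metaphyseal flare, mm (default 4).
#' @param angulation_deg Tilt of the distal fragment (growth plate and
#'   epiphysis) away from the diaphysis perpendicular; 0 = healthy,
#'   positive values emulate a dorsally angulated buckle pattern.
#' @param spacing Raster spacing, mm/pixel (default 0.1).
#' @param jitter_sd Vertex jitter (mm) applied by [corrupt_pair()].
#' @param dropout_fraction Contiguous arc fraction removed by
#'   [corrupt_pair()]; in `[0, 0.5)`.
#' @param theta_max_deg,trans_max_mm Bounds of the uniform random rigid
#'   perturbation of the moving view (defaults 20 deg, 20 mm).
#' @param flip `"always"` (default: the moving view is mirrored, as for an
#'   opposite-orientation scan), `"never"`, or `"random"`.
#' @param stroke_mm Rendered boundary thickness, mm (default 0.3).
#' @param seed Seed for the perturbation draw; `NULL` uses the current RNG
#'   state.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(diaphysis_length = 60, bone_width = 10,
                           physis_gap = 3, flare_height = 4,
                           angulation_deg = 0, spacing = 0.1,
                           jitter_sd = 0, dropout_fraction = 0,
                           theta_max_deg = 20, trans_max_mm = 20,
                           flip = c("always", "never", "random"),
                           stroke_mm = 0.3, seed = NULL) {
  stopifnot(diaphysis_length > 0, bone_width > 0, physis_gap > 0,
            flare_height > 0, spacing > 0, jitter_sd >= 0,
            dropout_fraction >= 0, dropout_fraction < 0.5,
            theta_max_deg >= 0, trans_max_mm >= 0, stroke_mm > 0)
  structure(list(diaphysis_length = diaphysis_length, bone_width = bone_width,
                 physis_gap = physis_gap, flare_height = flare_height,
                 angulation_deg = angulation_deg, spacing = spacing,
                 jitter_sd = jitter_sd, dropout_fraction = dropout_fraction,
                 theta_max_deg = theta_max_deg, trans_max_mm = trans_max_mm,
                 flip = match.arg(flip), stroke_mm = stroke_mm, seed = seed),
            class = "phantom_config")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# dense vertices of the fixed-frame main boundary curve and the tilted
# distal-fragment pieces; all mm
.phantom_geometry <- function(cfg, lm_cfg) {
  x0 <- 12; y_base <- 15
  fh <- cfg$flare_height
  fr <- 0.75 * fh
  P0 <- c(x0, y_base + fh)
  a <- cfg$angulation_deg * pi / 180
  Ra <- rigid_transform(theta = a)
  rot_about_P0 <- function(p) sweep(apply_point(Ra, sweep(p, 2, P0)), 2, P0, "+")

  flare <- rbind(P0,
                 c(x0 + 0.5 * fr, y_base + 0.3 * fh),
                 c(x0 + fr, y_base))
  xs <- seq(x0 + fr, x0 + fr + cfg$diaphysis_length, by = 1)
  if (xs[length(xs)] < x0 + fr + cfg$diaphysis_length)
    xs <- c(xs, x0 + fr + cfg$diaphysis_length)
  main <- rbind(flare, cbind(xs[-1], y_base))

  # epiphysis: short separate boundary beyond the physis gap, tilted with
  # the distal fragment
  e1 <- P0 + c(-cfg$physis_gap, 0.5)
  epi <- rot_about_P0(rbind(e1, e1 + c(-3, -0.8), e1 + c(-6, -2)))

  plate_dir <- apply_vector(Ra, c(0, 1))
  plate <- rbind(P0, P0 + cfg$bone_width * plate_dir)

  x_run0 <- x0 + fr
  xd1 <- x_run0 + lm_cfg$d1_percentile * cfg$diaphysis_length
  lm <- landmark_set(L_p = P0,
                     L_d0 = c(xd1 - lm_cfg$d0_arc_distance, y_base),
                     L_d1 = c(xd1, y_base))
  list(main = main, epi = epi, plate = plate, plate_dir = plate_dir,
       landmarks = lm, P0 = P0, y_base = y_base)
}

#' Generate a paired fixed/moving phantom with full ground truth
#'
#' @param cfg A [phantom_config()].
#' @param lm_cfg The [landmark_config()] whose placement conventions define
#'   the ground-truth diaphysis landmarks.
#' @param render Render binary masks (set `FALSE` when only the vector
#'   geometry is needed).
#' @return An object of class `phantom_pair`: lists `fixed` and `moving`
#'   (each with `polyline`, `pieces`, `epiphysis`, `landmarks`,
#'   `growth_plate`, `plate_dir` and, if rendered, `mask`), plus
#'   `true_transform` (moving -> fixed, including any pre-flip),
#'   `true_angulation_deg`, `perturbation` (the drawn displacement) and
#'   `spacing`.
#' @export
generate_pair <- function(cfg = phantom_config(), lm_cfg = landmark_config(),
                          render = TRUE) {
  stopifnot(inherits(cfg, "phantom_config"))
  .with_seed(cfg$seed, {
    g <- .phantom_geometry(cfg, lm_cfg)
    w <- cfg$bone_width

    shift_y <- function(p, dy) sweep(p, 2, c(0, -dy), "+")
    mv_main <- shift_y(g$main, w)
    mv_epi <- shift_y(g$epi, w)
    mv_plate <- shift_y(g$plate, w)
    mv_lm_fused <- rbind(g$landmarks$L_p, g$landmarks$L_d0, g$landmarks$L_d1)
    mv_lm_fused <- shift_y(mv_lm_fused, w)

    theta_p <- stats::runif(1, -cfg$theta_max_deg, cfg$theta_max_deg) * pi / 180
    t_p <- stats::runif(2, -cfg$trans_max_mm, cfg$trans_max_mm)
    flip <- switch(cfg$flip, always = TRUE, never = FALSE,
                   random = stats::runif(1) < 0.5)

    G0 <- rigid_transform(theta_p, t_p[1], t_p[2], pre_flip = flip)
    allpts <- apply_point(G0, rbind(mv_main, mv_epi))
    s <- c(5, 5) - c(min(allpts[, 1]), min(allpts[, 2]))
    G <- rigid_transform(theta_p, t_p[1] + s[1], t_p[2] + s[2], pre_flip = flip)

    mv_main_m <- apply_point(G, mv_main)
    mv_epi_m <- apply_point(G, mv_epi)
    mv_plate_m <- apply_point(G, mv_plate)
    mv_lm_m <- apply_point(G, mv_lm_fused)
    true_t <- matrix_to_transform(solve(to_matrix(G)))

    fixed <- list(polyline = polyline(g$main), pieces = list(polyline(g$main)),
                  epiphysis = polyline(g$epi),
                  landmarks = g$landmarks, growth_plate = g$plate,
                  plate_dir = g$plate_dir,
                  fused_targets = rbind(g$landmarks$L_p - c(0, w),
                                        g$landmarks$L_d0 - c(0, w),
                                        g$landmarks$L_d1 - c(0, w)))
    moving <- list(polyline = polyline(mv_main_m), pieces = list(polyline(mv_main_m)),
                   epiphysis = polyline(mv_epi_m),
                   landmarks = landmark_set(mv_lm_m[1, ], mv_lm_m[2, ], mv_lm_m[3, ]),
                   growth_plate = mv_plate_m,
                   plate_dir = apply_vector(G, g$plate_dir))

    pair <- structure(list(fixed = fixed, moving = moving,
                           true_transform = true_t,
                           true_angulation_deg = cfg$angulation_deg,
                           perturbation = list(theta_deg = theta_p * 180 / pi,
                                               t_mm = t_p, flip = flip),
                           spacing = cfg$spacing, config = cfg),
                      class = "phantom_pair")
    if (render) pair <- render_pair(pair)
    pair
  })
}

#' Rasterize the phantom boundary curves into binary masks
#' @param pair A [generate_pair()] result.
#' @return The pair with `fixed$mask` and `moving$mask` filled in.
#' @export
render_pair <- function(pair) {
  stopifnot(inherits(pair, "phantom_pair"))
  cfg <- pair$config
  ras <- function(side) {
    pls <- c(side$pieces, list(side$epiphysis))
    .rasterize(pls, cfg$spacing, cfg$stroke_mm)
  }
  pair$fixed$mask <- ras(pair$fixed)
  pair$moving$mask <- ras(pair$moving)
  pair
}

.rasterize <- function(polylines, spacing, stroke_mm, margin_mm = 3) {
  pts <- do.call(rbind, lapply(polylines, function(p) p$points))
  if (min(pts) - stroke_mm < 0) stop("geometry extends below the raster origin")
  xmax <- max(pts[, 1]) + margin_mm; ymax <- max(pts[, 2]) + margin_mm
  nc <- ceiling(xmax / spacing) + 1; nr <- ceiling(ymax / spacing) + 1
  m <- matrix(FALSE, nr, nc)
  rad <- max(1, round(stroke_mm / 2 / spacing))
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, ]
  for (pl in polylines) {
    dense <- polyline_to_pointset(pl, step = spacing / 2)
    rr <- round(dense[, 2] / spacing) + 1
    cc <- round(dense[, 1] / spacing) + 1
    for (j in seq_len(nrow(offs))) {
      r2 <- rr + offs$dr[j]; c2 <- cc + offs$dc[j]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      m[cbind(r2[ok], c2[ok])] <- TRUE
    }
  }
  boundary_mask(m, spacing)
}

#' Corrupt a phantom pair with vertex jitter and segment dropout
#'
#' Boundary polylines are resampled at 1 mm, Gaussian jitter is added to
#' each vertex, and (optionally) one contiguous arc segment is removed from
#' each main curve; masks are re-rendered. Ground truth (landmarks,
#' transform, angulation) is left unchanged, so the corrupted pair measures
#' the robustness of extraction and alignment to segmentation noise. With
#' zero jitter and zero dropout the pair is returned unchanged.
#'
#' @param pair A [generate_pair()] result.
#' @param jitter_sd Vertex jitter standard deviation, mm.
#' @param dropout_fraction Arc fraction removed, `[0, 0.5)`.
#' @param seed Seed for the noise draw.
#' @param render Re-render masks.
#' @return A `phantom_pair` with noisy boundaries.
#' @export
corrupt_pair <- function(pair, jitter_sd = pair$config$jitter_sd,
                         dropout_fraction = pair$config$dropout_fraction,
                         seed = NULL, render = !is.null(pair$fixed$mask)) {
  stopifnot(inherits(pair, "phantom_pair"),
            jitter_sd >= 0, dropout_fraction >= 0, dropout_fraction < 0.5)
  if (jitter_sd == 0 && dropout_fraction == 0) return(pair)
  .with_seed(seed, {
    noisy <- function(pl) {
      pts <- polyline_to_pointset(pl, step = 1)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sd), ncol = 2)
      n <- nrow(pts)
      if (dropout_fraction > 0 && n > 4) {
        k <- max(1, round(dropout_fraction * n))
        start <- sample.int(n - k + 1, 1)
        idx <- start:(start + k - 1)
        pieces <- list()
        if (min(idx) > 2) pieces <- c(pieces, list(pts[1:(min(idx) - 1), , drop = FALSE]))
        if (max(idx) < n - 1) pieces <- c(pieces, list(pts[(max(idx) + 1):n, , drop = FALSE]))
      } else pieces <- list(pts)
      pieces <- Filter(function(p) nrow(p) >= 2, pieces)
      if (!length(pieces)) stop("dropout removed the entire boundary")
      lapply(pieces, polyline)
    }
    for (side in c("fixed", "moving")) {
      pieces <- noisy(pair[[side]]$polyline)
      lens <- vapply(pieces, arc_length, numeric(1))
      pair[[side]]$pieces <- pieces
      pair[[side]]$polyline <- pieces[[which.max(lens)]]
    }
    if (render) pair <- render_pair(pair)
    pair
  })
}

#' Write a phantom pair to disk (masks, truth, polylines)
#'
#' Writes `fixed.png`, `moving.png` (with spacing sidecars), `truth.json`
#' (landmarks, true transform, angulation, perturbation) and
#' `polylines.json`.
#'
#' @param pair A rendered [generate_pair()] result.
#' @param dir Output directory (created if needed).
#' @export
write_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  if (is.null(pair$fixed$mask)) pair <- render_pair(pair)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(pair$fixed$mask, file.path(dir, "fixed.png"))
  write_mask(pair$moving$mask, file.path(dir, "moving.png"))
  lm_list <- function(lm) list(L_p = lm$L_p, L_d0 = lm$L_d0, L_d1 = lm$L_d1)
  truth <- list(
    spacing_mm = pair$spacing,
    true_angulation_deg = pair$true_angulation_deg,
    true_transform = jsonlite::fromJSON(transform_to_json(pair$true_transform)),
    perturbation = pair$perturbation,
    fixed_landmarks = lm_list(pair$fixed$landmarks),
    moving_landmarks = lm_list(pair$moving$landmarks),
    fixed_growth_plate = pair$fixed$growth_plate,
    moving_growth_plate = pair$moving$growth_plate)
  writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                           digits = I(12), pretty = TRUE)),
             file.path(dir, "truth.json"))
  pls <- list(fixed = lapply(pair$fixed$pieces, function(p) p$points),
              moving = lapply(pair$moving$pieces, function(p) p$points))
  writeLines(as.character(jsonlite::toJSON(pls, digits = I(12))),
             file.path(dir, "polylines.json"))
  invisible(dir)
}
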