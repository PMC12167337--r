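#' Alignment (pose estimation) configuration
#'
#' Weights and optimizer settings for the three-constraint alignment energy
#' `E = w_a * C_a + w_o * C_o + w_p * C_p`, where `C_a` aligns the two
#' physis points (x-components equal, y-components offset by `d`), `C_o`
#' makes the diaphysis unit directions parallel, and `C_p` places the moving
#' diaphysis midline at distance `w` (the bone width) from the fixed
#' diaphysis line.
#'
#' @param w_x,w_y Weights of the x- and y-distance terms inside `C_a`.
#' @param w_a,w_o,w_p Outer weights combining the three constraints.
#' @param d Target vertical physis offset, mm (default 10).
#' @param w Target bone width, mm; defaults to `d`. At `w = 0`, `C_p`
#'   reduces to the plain point-to-line distance.
#' @param learning_rate Gradient-descent step size (default 5e-2).
#' @param iterations Number of descent iterations (default 10000).
#' @param init `"diaphysis"` (default: closed-form start — rotation from the
#'   two diaphysis directions, translation placing the moving physis at its
#'   target — which the descent then refines), `"physis"` (zero rotation,
#'   physis-to-physis translation), `"identity"`, or a numeric
#'   `c(theta_rad, tx_mm, ty_mm)` in canonical about-the-origin form.
#' @param fd_step Central finite-difference step in each optimizer
#'   parameter (default 1e-4).
#' @param trace_every Record every n-th iteration in the trace (default 10).
#' @return An object of class `alignment_config`.
#' @export
alignment_config <- function(w_x = 1, w_y = 1, w_a = 1, w_o = 1, w_p = 1,
                             d = 10, w = NULL, learning_rate = 5e-2,
                             iterations = 10000, init = "diaphysis",
                             fd_step = 1e-4, trace_every = 10) {
  if (is.null(w)) w <- d
  stopifnot(w_x >= 0, w_y >= 0, w_a >= 0, w_o >= 0, w_p >= 0,
            d >= 0, w >= 0, learning_rate > 0, iterations >= 1,
            fd_step > 0, trace_every >= 1)
  if (is.numeric(init)) stopifnot(length(init) == 3) else
    init <- match.arg(init, c("diaphysis", "physis", "identity"))
  structure(list(w_x = w_x, w_y = w_y, w_a = w_a, w_o = w_o, w_p = w_p,
                 d = d, w = w, learning_rate = learning_rate,
                 iterations = as.integer(iterations), init = init,
                 fd_step = fd_step, trace_every = as.integer(trace_every)),
            class = "alignment_config")
}

#' Load an alignment configuration from YAML or JSON
#'
#' Recognized keys: `w_x, w_y, w_a, w_o, w_p, d_mm, width_mm,
#' learning_rate, iterations, init, fd_step, trace_every`. Missing keys
#' take the [alignment_config()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return An [alignment_config()].
#' @export
load_alignment_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: no such file: ", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  args <- list()
  map <- c(w_x = "w_x", w_y = "w_y", w_a = "w_a", w_o = "w_o", w_p = "w_p",
           d = "d_mm", w = "width_mm", learning_rate = "learning_rate",
           iterations = "iterations", init = "init", fd_step = "fd_step",
           trace_every = "trace_every")
  for (a in names(map)) if (!is.null(obj[[map[[a]]]])) args[[a]] <- obj[[map[[a]]]]
  do.call(alignment_config, args)
}

.lm_matrix <- function(lm) rbind(lm$L_p, lm$L_d0, lm$L_d1)

#' Latitudinal constraint: physis alignment
#'
#' `C_a = w_x * |L^f_px - T(L^m_p)_x| + w_y * |d - L^f_py + T(L^m_p)_y|`:
#' zero iff the transformed moving physis sits at the fixed physis
#' x-position with its y-component offset by `d`.
#'
#' @param Lf,Lm Fixed / moving [landmark_set()].
#' @param t A [rigid_transform()] (moving -> fixed).
#' @param cfg An [alignment_config()].
#' @return Non-negative scalar (mm-weighted).
#' @export
latitudinal_constraint <- function(Lf, Lm, t, cfg = alignment_config()) {
  tp <- apply_point(t, Lm$L_p)
  cfg$w_x * abs(Lf$L_p[1] - tp[1]) + cfg$w_y * abs(cfg$d - Lf$L_p[2] + tp[2])
}

#' Longitudinal orientation constraint: parallel diaphyses
#'
#' `C_o = || i^f_d - i^m_d ||` with `i^f_d = (L^f_d0 - L^f_d1) / ||.||` and
#' `i^m_d = T_linear(L^m_d0 - L^m_d1) / ||L^m_d0 - L^m_d1||` (linear part
#' only; the untransformed norm, which for a rigid transform equals the
#' transformed one). In `[0, 2]`: 0 for parallel, 2 for antiparallel.
#'
#' @inheritParams latitudinal_constraint
#' @export
orientation_constraint <- function(Lf, Lm, t) {
  vf <- Lf$L_d0 - Lf$L_d1
  nf <- sqrt(sum(vf^2))
  vm <- Lm$L_d0 - Lm$L_d1
  nm <- sqrt(sum(vm^2))
  if (nf == 0 || nm == 0) stop("zero-length diaphysis segment")
  im <- apply_vector(t, vm) / nm
  sqrt(sum((vf / nf - im)^2))
}

#' Longitudinal position constraint: bone-width spacing
#'
#' With `L^m_dmid` the midpoint of the moving diaphysis landmarks and `n^f`
#' the unit normal of the fixed diaphysis direction, returns
#' `| |(T(L^m_dmid) - L^f_d0) . n^f| - w |`: the unsigned distance from the
#' transformed moving midline to the fixed diaphysis line, minus the target
#' bone width `w`, in absolute value. `w = 0` gives the plain point-to-line
#' distance, which on its own admits the degenerate collinear minimum.
#'
#' @inheritParams latitudinal_constraint
#' @export
position_constraint <- function(Lf, Lm, t, cfg = alignment_config()) {
  vf <- Lf$L_d0 - Lf$L_d1
  nf <- sqrt(sum(vf^2))
  if (nf == 0) stop("zero-length fixed diaphysis segment")
  i_f <- vf / nf
  n_f <- c(-i_f[2], i_f[1])
  mid <- (Lm$L_d0 + Lm$L_d1) / 2
  dist <- abs(sum((apply_point(t, mid) - Lf$L_d0) * n_f))
  abs(dist - cfg$w)
}

#' Total alignment energy and its breakdown
#'
#' @inheritParams latitudinal_constraint
#' @return A list with components `C_a`, `C_o`, `C_p` and
#'   `E = w_a * C_a + w_o * C_o + w_p * C_p`.
#' @export
total_energy <- function(Lf, Lm, t, cfg = alignment_config()) {
  ca <- latitudinal_constraint(Lf, Lm, t, cfg)
  co <- orientation_constraint(Lf, Lm, t)
  cp <- position_constraint(Lf, Lm, t, cfg)
  list(C_a = ca, C_o = co, C_p = cp,
       E = cfg$w_a * ca + cfg$w_o * co + cfg$w_p * cp)
}

#' Estimate the moving-to-fixed transform by gradient descent
#'
#' Minimizes the weighted constraint energy over `(theta, tx, ty)` by
#' plain gradient descent with central finite-difference gradients. The
#' flip is not optimized: set `pre_flip = TRUE` to mirror the moving
#' landmarks about x = 0 before the rigid search (the returned transform
#' then carries `pre_flip = TRUE` and applies to the unmirrored moving
#' coordinates).
#'
#' Internally the rotation is parameterized about the moving physis point
#' and the angle coordinate is scaled by the landmark radius, so that a
#' unit step has comparable effect in all three coordinates; the returned
#' transform is in the canonical about-the-origin form. Because the energy
#' is a weighted sum of absolute values, plain descent ends in a small
#' oscillation around the minimum; the iterate with the lowest energy seen
#' is returned, as is standard for subgradient methods.
#'
#' @param Lf,Lm Fixed / moving [landmark_set()] (mm).
#' @param cfg An [alignment_config()].
#' @param pre_flip Mirror the moving landmarks about x = 0 before the
#'   rigid search.
#' @return A list: `transform` (the best [rigid_transform()]),
#'   `energy` (its [total_energy()] breakdown), `initial_energy`, and
#'   `trace` (data frame `iter, E, C_a, C_o, C_p, theta_deg, tx_mm, ty_mm`,
#'   strided by `cfg$trace_every`; the final row is the returned transform).
#' @export
optimize_alignment <- function(Lf, Lm, cfg = alignment_config(), pre_flip = FALSE) {
  stopifnot(inherits(Lf, "landmark_set"), inherits(Lm, "landmark_set"),
            inherits(cfg, "alignment_config"))
  Mf <- .lm_matrix(Lf)
  Mm <- .lm_matrix(Lm)
  if (pre_flip) Mm[, 1] <- -Mm[, 1]

  ctr <- Mm[1, ] # rotation centre: moving physis
  r <- max(1, mean(sqrt(rowSums(sweep(Mm[2:3, , drop = FALSE], 2, ctr)^2))))

  # initial (theta, ax, ay) in the centred parameterization:
  # T(p) = R(theta) (p - ctr) + ctr + (ax, ay)
  init <- cfg$init
  if (identical(init, "diaphysis")) {
    vf <- Mf[2, ] - Mf[3, ]
    vm <- Mm[2, ] - Mm[3, ]
    th0 <- atan2(vf[2], vf[1]) - atan2(vm[2], vm[1])
    if (th0 > pi) th0 <- th0 - 2 * pi
    if (th0 <= -pi) th0 <- th0 + 2 * pi
    u0 <- c(th0, Mf[1, 1] - ctr[1], Mf[1, 2] - cfg$d - ctr[2])
  } else if (identical(init, "physis")) {
    u0 <- c(0, Mf[1, ] - ctr)
  } else if (identical(init, "identity")) {
    th0 <- 0
    u0 <- c(0, 0, 0)
  } else {
    # numeric canonical (theta, tx, ty): convert the translation part
    th0 <- init[1]
    cs <- cos(th0); sn <- sin(th0)
    Rc <- c(cs * ctr[1] - sn * ctr[2], sn * ctr[1] + cs * ctr[2])
    u0 <- c(th0, init[2:3] - ctr + Rc)
  }

  res <- pose_gd_cpp(Mf, Mm, c(cfg$w_x, cfg$w_y, cfg$w_a, cfg$w_o, cfg$w_p),
                     cfg$d, cfg$w, cfg$learning_rate, cfg$iterations,
                     cfg$fd_step, ctr, r, u0, cfg$trace_every)

  canon <- function(theta, ax, ay) {
    cs <- cos(theta); sn <- sin(theta)
    tx <- ctr[1] + ax - (cs * ctr[1] - sn * ctr[2])
    ty <- ctr[2] + ay - (sn * ctr[1] + cs * ctr[2])
    c(theta, tx, ty)
  }
  tr <- res$trace
  can <- t(apply(tr[, 6:8, drop = FALSE], 1, function(p) canon(p[1], p[2], p[3])))
  trace <- data.frame(iter = as.integer(tr[, 1]), E = tr[, 2], C_a = tr[, 3],
                      C_o = tr[, 4], C_p = tr[, 5],
                      theta_deg = can[, 1] * 180 / pi,
                      tx_mm = can[, 2], ty_mm = can[, 3])
  bp <- canon(res$best[1], res$best[2], res$best[3])
  transform <- rigid_transform(theta = bp[1], tx = bp[2], ty = bp[3],
                               pre_flip = pre_flip)
  list(transform = transform,
       energy = total_energy(Lf, Lm, transform, cfg),
       initial_energy = res$E0,
       trace = trace)
}
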