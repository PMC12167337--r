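test_that("latitudinal constraint matches its printed examples", {
  cfg <- alignment_config(d = 4)
  # transformed moving physis exactly at (fixed x, fixed y - d): zero
  Lf <- landmark_set(c(10, 20), c(20, 20), c(45, 20))
  Lm <- landmark_set(c(10, 16), c(20, 16), c(45, 16))
  expect_equal(latitudinal_constraint(Lf, Lm, rigid_transform(), cfg), 0)

  cfg0 <- alignment_config(d = 0)
  Lf2 <- landmark_set(c(0, 0), c(5, 0), c(30, 0))
  Lm2 <- landmark_set(c(3, 4), c(5, 4), c(30, 4))
  expect_equal(latitudinal_constraint(Lf2, Lm2, rigid_transform(), cfg0), 7)
  cfg2 <- alignment_config(w_x = 2, d = 0)
  expect_equal(latitudinal_constraint(Lf2, Lm2, rigid_transform(), cfg2), 10)
})

test_that("orientation constraint is 0 / sqrt(2) / 2 for parallel, perpendicular, antiparallel", {
  Lf <- landmark_set(c(0, 5), c(0, 0), c(10, 0))
  para <- landmark_set(c(0, 5), c(5, 0), c(15, 0))
  perp <- landmark_set(c(5, 0), c(0, 0), c(0, 10))
  anti <- landmark_set(c(0, 5), c(10, 0), c(0, 0))
  id <- rigid_transform()
  expect_equal(orientation_constraint(Lf, para, id), 0)
  expect_equal(orientation_constraint(Lf, perp, id), sqrt(2))
  expect_equal(orientation_constraint(Lf, anti, id), 2)
})

test_that("position constraint measures midline distance minus bone width", {
  Lf <- landmark_set(c(-5, 5), c(0, 0), c(10, 0)) # fixed diaphysis on the x-axis
  Lm <- landmark_set(c(-5, 9), c(0, 9), c(10, 9)) # midpoint at (5, 9)
  expect_equal(position_constraint(Lf, Lm, rigid_transform(),
                                   alignment_config(w = 7)), 2)
  # w = 0 reduces to the plain point-to-line distance
  expect_equal(position_constraint(Lf, Lm, rigid_transform(),
                                   alignment_config(w = 0)), 9)
  # midline exactly at w: zero
  expect_equal(position_constraint(Lf, Lm, rigid_transform(),
                                   alignment_config(w = 9)), 0)
})

test_that("total energy is the weighted sum and drops terms with zero weight", {
  set.seed(31)
  Lf <- random_landmarks(); Lm <- random_landmarks()
  t <- rigid_transform(0.4, 3, -2)
  cfg <- alignment_config(w_a = 1.5, w_o = 0.5, w_p = 2, d = 6, w = 9)
  e <- total_energy(Lf, Lm, t, cfg)
  expect_equal(e$E, 1.5 * e$C_a + 0.5 * e$C_o + 2 * e$C_p, tolerance = 1e-12)
  cfg0 <- alignment_config(w_a = 1.5, w_o = 0, w_p = 2, d = 6, w = 9)
  e0 <- total_energy(Lf, Lm, t, cfg0)
  expect_equal(e0$E, e$E - 0.5 * e$C_o, tolerance = 1e-12)
})

test_that("constraints match independent brute-force oracles on random instances", {
  set.seed(32)
  for (i in 1:1000) {
    Lf <- random_landmarks(); Lm <- random_landmarks()
    theta <- runif(1, -pi, pi); tx <- runif(1, -30, 30); ty <- runif(1, -30, 30)
    flip <- runif(1) < 0.5
    t <- rigid_transform(theta, tx, ty, pre_flip = flip)
    w_x <- runif(1, 0, 2); w_y <- runif(1, 0, 2)
    d <- runif(1, 0, 15); w <- runif(1, 0, 15)
    cfg <- alignment_config(w_x = w_x, w_y = w_y, d = d, w = w)
    expect_equal(latitudinal_constraint(Lf, Lm, t, cfg),
                 oracle_latitudinal(Lf$L_p, Lm$L_p, theta, tx, ty, flip,
                                    w_x, w_y, d), tolerance = 1e-9)
    expect_equal(orientation_constraint(Lf, Lm, t),
                 oracle_orientation(Lf$L_d0, Lf$L_d1, Lm$L_d0, Lm$L_d1,
                                    theta, flip), tolerance = 1e-9)
    expect_equal(position_constraint(Lf, Lm, t, cfg),
                 oracle_position(Lf$L_d0, Lf$L_d1, Lm$L_d0, Lm$L_d1,
                                 theta, tx, ty, flip, w), tolerance = 1e-9)
  }
})

test_that("constraints are non-negative and C_o bounded by 2", {
  set.seed(33)
  for (i in 1:200) {
    Lf <- random_landmarks(); Lm <- random_landmarks()
    t <- rigid_transform(runif(1, -pi, pi), runif(1, -30, 30),
                         runif(1, -30, 30), pre_flip = runif(1) < 0.5)
    e <- total_energy(Lf, Lm, t, alignment_config(d = 5))
    expect_gte(e$C_a, 0); expect_gte(e$C_o, 0); expect_gte(e$C_p, 0)
    expect_lte(e$C_o, 2 + 1e-12)
  }
})

test_that("descent recovers the ground-truth transform on noiseless phantoms", {
  cfg <- phantom_alignment_config()
  for (s in 1:8) {
    p <- generate_pair(phantom_config(seed = s, flip = "random"), render = FALSE)
    fit <- optimize_alignment(p$fixed$landmarks, p$moving$landmarks, cfg,
                              pre_flip = p$true_transform$pre_flip)
    errs <- recovery_errors(p, fit$transform)
    expect_lt(max(errs), 1) # every landmark within 1 mm
    dth <- abs(fit$transform$theta - p$true_transform$theta) * 180 / pi
    expect_lt(dth, 1)
    expect_lte(fit$energy$E, fit$initial_energy + 1e-12)
  }
})

test_that("descent refines noisy landmark configurations", {
  set.seed(34)
  cfg <- phantom_alignment_config(init = "physis")
  p <- generate_pair(phantom_config(seed = 101), render = FALSE)
  lm <- p$moving$landmarks
  jit <- lapply(list(lm$L_p, lm$L_d0, lm$L_d1), function(q) q + rnorm(2, 0, 0.4))
  lmn <- landmark_set(jit[[1]], jit[[2]], jit[[3]])
  fit <- optimize_alignment(p$fixed$landmarks, lmn, cfg, pre_flip = TRUE)
  expect_lt(fit$energy$E, 0.25 * fit$initial_energy)
})

test_that("an already-optimal start is a stationary point of the descent", {
  p <- generate_pair(phantom_config(seed = 5), render = FALSE)
  tt <- p$true_transform
  cfg <- phantom_alignment_config(init = c(tt$theta, tt$tx, tt$ty),
                                  iterations = 200)
  fit <- optimize_alignment(p$fixed$landmarks, p$moving$landmarks, cfg,
                            pre_flip = tt$pre_flip)
  expect_lt(abs(fit$transform$theta - tt$theta), 1e-6)
  expect_lt(abs(fit$transform$tx - tt$tx), 1e-6)
  expect_lt(abs(fit$transform$ty - tt$ty), 1e-6)
})

test_that("optimization is deterministic and the trace ends at the returned transform", {
  p <- generate_pair(phantom_config(seed = 9), render = FALSE)
  cfg <- phantom_alignment_config(iterations = 500)
  f1 <- optimize_alignment(p$fixed$landmarks, p$moving$landmarks, cfg, pre_flip = TRUE)
  f2 <- optimize_alignment(p$fixed$landmarks, p$moving$landmarks, cfg, pre_flip = TRUE)
  expect_identical(f1$trace, f2$trace)
  expect_identical(to_matrix(f1$transform), to_matrix(f2$transform))
  last <- f1$trace[nrow(f1$trace), ]
  expect_equal(last$theta_deg, f1$transform$theta * 180 / pi, tolerance = 1e-9)
  expect_equal(c(last$tx_mm, last$ty_mm), c(f1$transform$tx, f1$transform$ty),
               tolerance = 1e-9)
  expect_equal(last$E, f1$energy$E, tolerance = 1e-9)
  expect_lte(nrow(f1$trace), cfg$iterations + 2)
})

test_that("translating both landmark sets shifts the solution consistently", {
  cfg <- phantom_alignment_config()
  p <- generate_pair(phantom_config(seed = 12), render = FALSE)
  shift <- c(7, -3)
  sh <- function(lm) landmark_set(lm$L_p + shift, lm$L_d0 + shift, lm$L_d1 + shift)
  f0 <- optimize_alignment(p$fixed$landmarks, p$moving$landmarks, cfg, pre_flip = TRUE)
  f1 <- optimize_alignment(sh(p$fixed$landmarks), sh(p$moving$landmarks), cfg,
                           pre_flip = TRUE)
  expect_equal(f1$transform$theta, f0$transform$theta, tolerance = 1e-6)
  # transformed moving physis must shift by exactly the common translation
  q0 <- apply_point(f0$transform, p$moving$landmarks$L_p)
  q1 <- apply_point(f1$transform, p$moving$landmarks$L_p + shift)
  expect_equal(q1, q0 + shift, tolerance = 1e-6)
})

test_that("alignment config loads from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("w_x: 2", "d_mm: 8", "width_mm: 12", "iterations: 50",
               "learning_rate: 0.01"), y)
  cfg <- load_alignment_config(y)
  expect_equal(cfg$w_x, 2); expect_equal(cfg$d, 8); expect_equal(cfg$w, 12)
  expect_equal(cfg$iterations, 50L); expect_equal(cfg$learning_rate, 0.01)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"w_o": 0.5, "d_mm": 6}', j)
  cfg2 <- load_alignment_config(j)
  expect_equal(cfg2$w_o, 0.5); expect_equal(cfg2$w, 6) # width defaults to d
})
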