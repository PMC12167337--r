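make_line_mask <- function(npx = 50, thick = 1, spacing = 0.1, nr = 20) {
  m <- matrix(FALSE, nr, npx + 10)
  rows <- 10 + seq_len(thick) - ceiling(thick / 2)
  m[rows, 5 + seq_len(npx)] <- TRUE
  boundary_mask(m, spacing)
}

test_that("a one-pixel line becomes a polyline of the expected length", {
  pl <- mask_to_polyline(make_line_mask(50, thick = 1))
  expect_s3_class(pl, "polyline")
  expect_equal(arc_length(pl), 49 * 0.1, tolerance = 1e-9)
  # ordered from the left end, converted to mm
  expect_lt(pl$points[1, 1], pl$points[nrow(pl$points), 1])
})

test_that("a thick line thins to the same centerline within one pixel", {
  sp <- 0.1
  thin1 <- mask_to_polyline(make_line_mask(60, thick = 1, spacing = sp))
  thin3 <- mask_to_polyline(make_line_mask(60, thick = 3, spacing = sp))
  # compare on the common x-extent to ignore end effects
  common <- intersect(round(thin1$points[, 1], 6), round(thin3$points[, 1], 6))
  y1 <- thin1$points[round(thin1$points[, 1], 6) %in% common, 2]
  y3 <- thin3$points[round(thin3$points[, 1], 6) %in% common, 2]
  expect_lte(max(abs(y1 - y3)), sp + 1e-9)
})

test_that("only the largest component is kept; empty and branched masks fail", {
  m <- matrix(FALSE, 30, 80)
  m[10, 5:70] <- TRUE   # long line
  m[25, 5:15] <- TRUE   # short separate line
  pl <- mask_to_polyline(boundary_mask(m, 0.1))
  expect_equal(arc_length(pl), 65 * 0.1, tolerance = 1e-9)
  expect_true(all(abs(pl$points[, 2] - 9 * 0.1) < 1e-9))

  expect_error(boundary_mask(matrix(FALSE, 5, 5), 0.1), "no boundary")

  y <- matrix(FALSE, 60, 60)
  y[30, 5:55] <- TRUE
  y[5:30, 30] <- TRUE   # long vertical branch -> three endpoints
  expect_error(mask_to_polyline(boundary_mask(y, 0.1)),
               "ambiguous boundary topology")
})

test_that("short spurs are pruned before the topology check", {
  m <- matrix(FALSE, 60, 120)
  m[30, 5:115] <- TRUE
  m[26:30, 60] <- TRUE  # 0.5 mm spur at 0.1 mm spacing
  pl <- mask_to_polyline(boundary_mask(m, 0.1), prune_mm = 2)
  expect_equal(arc_length(pl), 110 * 0.1, tolerance = 0.05)
})

test_that("landmarks on a straight horizontal polyline follow the placement rules", {
  line <- polyline(cbind(seq(0, 60, by = 0.5), 10))
  lm <- extract_landmarks(line, landmark_config(d0_arc_distance = 25))
  expect_equal(lm$L_d1[1], 54, tolerance = 0.3)      # 90th percentile of x
  expect_equal(sqrt(sum((lm$L_d0 - lm$L_d1)^2)), 25, tolerance = 1e-6)
  expect_equal(lm$L_p, c(0, 10), tolerance = 1e-9)   # lower-left = left end
})

test_that("extraction errors are informative", {
  short <- polyline(cbind(seq(0, 10, by = 0.5), 0))
  expect_error(extract_landmarks(short), "insufficient boundary extent")
  steep <- polyline(cbind(seq(0, 30, by = 0.25), seq(0, 60, by = 0.5)))
  expect_error(extract_landmarks(steep), "diaphysis not found")
})

test_that("mirrored polylines yield exactly mirrored landmarks", {
  p <- generate_pair(phantom_config(seed = 42), render = FALSE)
  pl <- p$fixed$polyline
  lm <- extract_landmarks(pl)
  mir <- polyline(cbind(-pl$points[, 1], pl$points[, 2]))
  lm_m <- extract_landmarks(mir, landmark_config(physis_side = "right"))
  expect_equal(lm_m$L_p, c(-lm$L_p[1], lm$L_p[2]), tolerance = 1e-9)
  expect_equal(lm_m$L_d0, c(-lm$L_d0[1], lm$L_d0[2]), tolerance = 1e-9)
  expect_equal(lm_m$L_d1, c(-lm$L_d1[1], lm$L_d1[2]), tolerance = 1e-9)
})

test_that("extraction is deterministic and spacing-covariant", {
  p <- generate_pair(phantom_config(seed = 7))
  a <- extract_landmarks(mask_to_polyline(p$fixed$mask))
  b <- extract_landmarks(mask_to_polyline(p$fixed$mask))
  expect_identical(a, b)

  # scaling the physical spacing scales the polyline exactly
  m <- p$fixed$mask
  pl1 <- mask_to_polyline(m)
  pl2 <- mask_to_polyline(boundary_mask(m$pixels, m$spacing * 2))
  expect_equal(pl2$points, pl1$points * 2, tolerance = 1e-12)
  # and with all mm config parameters scaled alike, landmarks scale exactly
  cfg1 <- landmark_config()
  cfg2 <- landmark_config(d0_arc_distance = cfg1$d0_arc_distance * 2,
                          min_diaphysis_length = cfg1$min_diaphysis_length * 2,
                          resample_step = cfg1$resample_step * 2)
  lm1 <- extract_landmarks(pl1, cfg1)
  lm2 <- extract_landmarks(pl2, cfg2)
  expect_equal(lm2$L_p, lm1$L_p * 2, tolerance = 1e-9)
  expect_equal(lm2$L_d1, lm1$L_d1 * 2, tolerance = 1e-9)
})

test_that("noiseless phantom landmarks are recovered within 1.5 mm", {
  set.seed(44)
  errs <- c()
  for (i in 1:100) {
    cfg <- phantom_config(diaphysis_length = runif(1, 50, 70),
                          bone_width = runif(1, 8, 14),
                          flare_height = runif(1, 3, 6),
                          angulation_deg = runif(1, 0, 15),
                          seed = 1000 + i)
    p <- generate_pair(cfg, render = FALSE)
    lm <- extract_landmarks(p$fixed$polyline)
    g <- p$fixed$landmarks
    errs <- c(errs, sqrt(sum((lm$L_p - g$L_p)^2)),
              sqrt(sum((lm$L_d0 - g$L_d0)^2)),
              sqrt(sum((lm$L_d1 - g$L_d1)^2)))
  }
  expect_lte(stats::quantile(errs, 0.95, names = FALSE), 1.5)
})

test_that("landmark JSON files round-trip and reject bad schemas", {
  lm <- landmark_set(c(1.5, 2), c(3, 4), c(30, 4.5))
  path <- withr::local_tempfile(fileext = ".json")
  landmarks_to_file(lm, path)
  lm2 <- landmarks_from_file(path)
  expect_equal(lm2$L_p, lm$L_p); expect_equal(lm2$L_d1, lm$L_d1)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"L_d0": [1, 2], "L_d1": [3, 4]}', bad)
  expect_error(landmarks_from_file(bad), "L_p")
  writeLines('{"L_p": [1], "L_d0": [1, 2], "L_d1": [3, 4]}', bad)
  expect_error(landmarks_from_file(bad), "pair")
})
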