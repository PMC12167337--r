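# Independent brute-force oracles: plain trigonometry and double loops,
# sharing no code with the package implementation.

oracle_transform_point <- function(p, theta, tx, ty, flip = FALSE) {
  x <- if (flip) -p[1] else p[1]
  y <- p[2]
  c(cos(theta) * x - sin(theta) * y + tx,
    sin(theta) * x + cos(theta) * y + ty)
}

oracle_latitudinal <- function(Lf_p, Lm_p, theta, tx, ty, flip, w_x, w_y, d) {
  q <- oracle_transform_point(Lm_p, theta, tx, ty, flip)
  w_x * abs(Lf_p[1] - q[1]) + w_y * abs(d - Lf_p[2] + q[2])
}

oracle_orientation <- function(Lf_d0, Lf_d1, Lm_d0, Lm_d1, theta, flip) {
  vf <- Lf_d0 - Lf_d1
  i_f <- vf / sqrt(sum(vf^2))
  vm <- Lm_d0 - Lm_d1
  if (flip) vm[1] <- -vm[1]
  rv <- c(cos(theta) * vm[1] - sin(theta) * vm[2],
          sin(theta) * vm[1] + cos(theta) * vm[2])
  im <- rv / sqrt(sum((Lm_d0 - Lm_d1)^2))
  sqrt(sum((i_f - im)^2))
}

oracle_position <- function(Lf_d0, Lf_d1, Lm_d0, Lm_d1, theta, tx, ty, flip, w) {
  vf <- Lf_d0 - Lf_d1
  i_f <- vf / sqrt(sum(vf^2))
  n_f <- c(-i_f[2], i_f[1])
  mid <- (Lm_d0 + Lm_d1) / 2
  q <- oracle_transform_point(mid, theta, tx, ty, flip)
  abs(abs(sum((q - Lf_d0) * n_f)) - w)
}

oracle_hausdorff <- function(A, B) {
  worst <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    worst <- max(worst, best)
  }
  worst
}

oracle_chamfer <- function(A, B) {
  nn <- function(P, Q) {
    s <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q)))
        best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
      s <- s + best
    }
    s / nrow(P)
  }
  0.5 * (nn(A, B) + nn(B, A))
}

random_landmarks <- function() {
  repeat {
    m <- matrix(runif(6, -50, 50), 3, 2)
    if (sqrt(sum((m[2, ] - m[3, ])^2)) > 1) break
  }
  landmark_set(m[1, ], m[2, ], m[3, ])
}
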