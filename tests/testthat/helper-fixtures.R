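# Shared fixtures: reference bowls, a default camera, and oracles used
# across test files.

ref_bowls <- function() {
  list(bowl_model(R = 64, H = 51, q = 6.3),
       bowl_model(R = 102, H = 71.5, q = 9.0),
       bowl_model(R = 80, H = 32, q = 3.5),
       bowl_model(R = 55, H = 44, q = 5.2),
       bowl_model(R = 130, H = 78, q = 8.5))
}

random_bowl <- function() {
  bowl_model(R = runif(1, 30, 130), H = runif(1, 9, 130), q = runif(1, 2, 10))
}

# Brute-force polyline arc length: sum of chord lengths on a dense grid.
polyline_arc_length <- function(bowl, n = 1e6) {
  y <- seq(0, bowl$R, length.out = n + 1)
  z <- (y / bowl$R)^bowl$q * bowl$H
  2 * sum(sqrt(diff(y)^2 + diff(z)^2))
}

# Independent axis-angle (Rodrigues) rotation about a principal axis.
rodrigues_axis <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Homogeneous 3x4 projection-matrix oracle.
project_homogeneous <- function(intr, pose, pts) {
  K <- rbind(c(intr$F, 0, intr$cx), c(0, intr$F, intr$cy), c(0, 0, 1))
  R <- rodrigues_axis("z", pose$psi) %*% rodrigues_axis("y", pose$theta) %*%
    rodrigues_axis("x", pose$phi)
  P <- K %*% cbind(R, pose$t)
  ph <- P %*% rbind(t(pts), 1)
  t(ph[1:2, , drop = FALSE] / rep(ph[3, ], each = 2))
}

# A camera pose looking at the bowl from a moderate tilt; visible with the
# default intrinsics for all reference bowls.
default_test_pose <- function() camera_pose(phi = 10, theta = 60, psi = -15,
                                            t = c(30, -20, 380))
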