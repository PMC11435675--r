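test_that("the forward model reproduces the simulator's 3D landmarks", {
  b <- bowl_model(R = 64, H = 51, q = 6.3)
  tape <- tape_spec()
  lm_sim <- landmark_pairs(b, tape)
  lm_fwd <- forward_landmarks(b, tape, lm_sim$arc_positions, lm_sim$L,
                              resolution = 10000)
  expect_lt(max(abs(lm_fwd$points - lm_sim$points)), 1e-3)
  expect_equal(lm_fwd$n_clamped, 0)
  # tape midpoint anchors at the bowl bottom
  mid <- forward_landmarks(b, tape, lm_sim$L / 2, lm_sim$L)
  expect_equal(unname(mid$points[1, 1:2]), c(2.5, 0), tolerance = 1e-6)
})

test_that("arc positions beyond a short candidate's curve are clamped and counted", {
  small <- bowl_model(R = 40, H = 20, q = 3)   # L_est < L_gt below
  tape <- tape_spec()
  L_gt <- 200
  s <- seq(0, L_gt, length.out = 21)
  fwd <- forward_landmarks(small, tape, s, L_gt)
  L_est <- fwd$L_est
  expect_lt(L_est, L_gt)
  expected_out <- sum(s - L_gt / 2 + L_est / 2 < 0 |
                        s - L_gt / 2 + L_est / 2 > L_est)
  expect_equal(fwd$n_clamped, expected_out)
  expect_gt(fwd$n_clamped, 0)
})

test_that("reprojection cost is zero at truth and additive per point", {
  b <- bowl_model(R = 80, H = 32, q = 3.5)
  intr <- camera_intrinsics(); tape <- tape_spec()
  pose <- default_test_pose()
  obs <- simulate_observation(b, tape, intr, pose)
  # match the simulator resolution where the check is about exactness
  hi <- estimation_config(resolution = 10000)
  expect_lt(reprojection_cost(b, pose, intr, obs, tape, hi), 1e-7)
  # a single 3-4-5 offset adds exactly 25 px^2
  obs2 <- obs
  obs2$points[7, ] <- obs2$points[7, ] + c(3, 4)
  expect_equal(reprojection_cost(b, pose, intr, obs2, tape, hi), 25,
               tolerance = 1e-4)
  # matches an independent per-point loop
  obs3 <- obs
  set.seed(13)
  obs3$points <- obs3$points + matrix(rnorm(length(obs3$points)),
                                      nrow(obs3$points))
  lm3 <- landmark_pairs(b, tape)
  px <- project_points(intr, pose, lm3$points)
  J_loop <- 0
  for (i in seq_len(nrow(px)))
    J_loop <- J_loop + sum((px[i, ] - obs3$points[i, ])^2)
  expect_equal(reprojection_cost(b, pose, intr, obs3, tape, hi), J_loop,
               tolerance = 1e-4)
})

test_that("LM pose fitting recovers the camera from noiseless data", {
  b <- bowl_model(R = 102, H = 71.5, q = 9)
  intr <- camera_intrinsics(); tape <- tape_spec()
  hi <- estimation_config(resolution = 10000)
  set.seed(17)
  for (i in 1:3) {
    sc <- random_scenario(bowl = b, intr = intr, tape = tape)
    obs <- simulate_observation(b, tape, intr, sc$pose)
    # from the true pose: stays put
    f0 <- fit_pose(b, intr, obs, tape, init_poses = list(sc$pose),
                   config = hi)
    expect_lt(f0$J, 1e-6)
    expect_lt(abs(f0$pose$theta - sc$pose$theta), 1e-4)
    expect_lt(max(abs(f0$pose$t - sc$pose$t)), 1e-3)
    # from the default multi-start set
    fm <- fit_pose(b, intr, obs, tape, config = hi)
    expect_lt(fm$J, 1e-3)
    # a clearly wrong bowl cannot fit as well
    wrong <- bowl_model(R = b$R * 1.2, H = b$H, q = b$q)
    fw <- fit_pose(wrong, intr, obs, tape, config = hi)
    expect_gt(fw$J, fm$J)
  }
})

test_that("selection errors decompose as stated", {
  b <- bowl_model(R = 64, H = 51, q = 6.3)
  intr <- camera_intrinsics(); tape <- tape_spec()
  pose <- default_test_pose()
  obs <- simulate_observation(b, tape, intr, pose)
  hi <- estimation_config(resolution = 10000)
  s0 <- selection_errors(b, pose, intr, obs, tape, hi)
  expect_lt(s0$e_l, 1e-6)
  expect_lt(s0$e_c, 1e-6)
  expect_lt(s0$e_n, 1e-5)
  # displace every observed point by d along its pair axis
  n2 <- nrow(obs$points) / 2
  axis <- obs$points[1:n2, ] - obs$points[n2 + 1:n2, ]
  W <- sqrt(rowSums(axis^2))
  unit <- axis / W
  d <- 2.5
  obs_d <- obs
  obs_d$points <- obs$points + rbind(unit, unit) * d
  sd1 <- selection_errors(b, pose, intr, obs_d, tape, hi)
  expect_equal(sd1$e_c, mean(2 * d / W), tolerance = 1e-5)
  expect_equal(sd1$e_n, sd1$e_c + sd1$e_l, tolerance = 1e-12)
  # e_n = e_c + e_l on random perturbations
  set.seed(29)
  obs_r <- obs
  obs_r$points <- obs$points + matrix(rnorm(length(obs$points), 0, 2),
                                      nrow(obs$points))
  wrongish <- bowl_model(R = 70, H = 48, q = 5)
  sr <- selection_errors(wrongish, pose, intr, obs_r, tape, hi)
  expect_equal(sr$e_n, sr$e_c + sr$e_l, tolerance = 1e-12)
})

test_that("a bowl on the coarse grid is recovered without refinement", {
  b <- bowl_model(R = 60, H = 50, q = 6)   # exactly on the default grid
  intr <- camera_intrinsics(); tape <- tape_spec()
  set.seed(19)
  sc <- random_scenario(bowl = b, intr = intr, tape = tape)
  obs <- simulate_observation(b, tape, intr, sc$pose)
  est <- estimate_bowl(obs, intr, tape, estimation_config(seed = 5))
  expect_lt(est$e_n, estimation_config()$threshold)
  expect_equal(est$rounds, 0)
  expect_equal(est$bowl$R, 60, tolerance = 1e-6)
  expect_equal(est$bowl$H, 50, tolerance = 1e-6)
  expect_equal(est$bowl$q, 6, tolerance = 1e-6)
})

test_that("refinement improves monotonically and is seed-deterministic", {
  b <- bowl_model(R = 87.5, H = 43, q = 2.3)   # off-grid bowl
  intr <- camera_intrinsics(); tape <- tape_spec()
  set.seed(23)
  sc <- random_scenario(bowl = b, intr = intr, tape = tape)
  obs <- simulate_observation(b, tape, intr, sc$pose)
  est1 <- estimate_bowl(obs, intr, tape, estimation_config(seed = 9))
  est2 <- estimate_bowl(obs, intr, tape, estimation_config(seed = 9))
  expect_identical(est1$bowl, est2$bowl)
  expect_identical(est1$trace, est2$trace)
  expect_true(all(diff(est1$trace) <= 1e-12))
  expect_equal(est1$e_n, est1$e_c + est1$e_l, tolerance = 1e-12)
  expect_equal(est1$volume, bowl_volume(est1$bowl))
  # parameters land near truth on noiseless data
  expect_lt(abs(est1$bowl$R - b$R) / b$R, 0.05)
  expect_lt(abs(est1$bowl$H - b$H) / b$H, 0.05)
})

test_that("the estimate is self-consistent under re-simulation", {
  b <- bowl_model(R = 55, H = 44, q = 5.2)
  intr <- camera_intrinsics(); tape <- tape_spec()
  set.seed(37)
  sc <- random_scenario(bowl = b, intr = intr, tape = tape)
  obs <- simulate_observation(b, tape, intr, sc$pose)
  est <- estimate_bowl(obs, intr, tape, estimation_config(seed = 3))
  # observing the returned bowl from the returned pose reproduces e_n ~ 0
  obs2 <- simulate_observation(est$bowl, tape, intr, est$pose)
  s2 <- selection_errors(est$bowl, est$pose, intr, obs2, tape,
                         estimation_config(resolution = 10000))
  expect_lt(s2$e_c, 1e-6)
  expect_lt(s2$e_n, 1e-5 + s2$e_l)
})

test_that("estimation results serialize to JSON", {
  b <- bowl_model(R = 60, H = 50, q = 6)
  intr <- camera_intrinsics(); tape <- tape_spec()
  set.seed(41)
  sc <- random_scenario(bowl = b, intr = intr, tape = tape)
  obs <- simulate_observation(b, tape, intr, sc$pose)
  est <- estimate_bowl(obs, intr, tape, estimation_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_result_json(est, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$bowl$R_mm, est$bowl$R)
  expect_equal(x$volume_cm3, est$volume)
  expect_equal(x$e_n, est$e_n)
})
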