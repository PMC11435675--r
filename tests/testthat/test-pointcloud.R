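test_that("ASCII PLY, XYZ and CSV clouds load identically", {
  set.seed(6)
  pts <- matrix(round(runif(60, -50, 50), 3), ncol = 3)
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header",
               apply(pts, 1, paste, collapse = " ")), ply)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write.table(pts, xyz, row.names = FALSE, col.names = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(setNames(as.data.frame(pts), c("x", "y", "z")), csv,
            row.names = FALSE)
  expect_equal(read_point_cloud(ply), pts, tolerance = 1e-6)
  expect_equal(read_point_cloud(xyz), pts, tolerance = 1e-6)
  expect_equal(read_point_cloud(csv), pts, tolerance = 1e-6)
})

test_that("PLY reading respects property order and rejects binary files", {
  pts <- cbind(1:3, 4:6, 7:9)
  ply <- withr::local_tempfile(fileext = ".ply")
  # z declared first: columns must be re-ordered on read
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float z", "property float x", "property float y",
               "end_header",
               apply(cbind(pts[, 3], pts[, 1], pts[, 2]), 1,
                     paste, collapse = " ")), ply)
  expect_equal(read_point_cloud(ply), pts, tolerance = 1e-12,
               ignore_attr = TRUE)
  bin <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 1", "property float x", "end_header"), bin)
  expect_error(read_point_cloud(bin), "ASCII")
})

test_that("a synthetic bowl cloud round-trips through slicing", {
  b <- bowl_model(R = 60, H = 45, q = 4.5)
  cloud <- synthesize_bowl_cloud(b, n = 80000, seed = 8)
  # thin slab: folding uses r = |y|, so slab thickness bounds the radial
  # approximation error near the axis
  prof <- extract_cross_section(cloud, slab_halfwidth = 0.5)
  # profile heights match the generating model
  z_model <- (pmin(prof$r, b$R) / b$R)^b$q * b$H
  expect_lt(mean(abs(prof$z - z_model)), 0.05)
  expect_equal(prof$H_obs, b$H, tolerance = 0.5)
  expect_error(extract_cross_section(cloud, slab_halfwidth = 0),
               "empty slab|positive")
})

test_that("slicing is robust to a tilted, off-center scan", {
  b <- bowl_model(R = 70, H = 50, q = 6)
  cloud <- synthesize_bowl_cloud(b, n = 80000, seed = 12)
  Rt <- rotation_from_euler(7, -4, 30)
  tilted <- cloud %*% t(Rt) + matrix(c(15, -8, 3), nrow(cloud), 3,
                                     byrow = TRUE)
  prof <- extract_cross_section(tilted, slab_halfwidth = 0.5)
  z_model <- (pmin(prof$r, b$R) / b$R)^b$q * b$H
  expect_lt(mean(abs(prof$z - z_model)), 0.25)
  # folded profile is left/right consistent: the fit sees one branch
  expect_true(all(prof$r >= 0))
})

test_that("free fitting recovers a noiseless power-law profile", {
  b <- bowl_model(R = 75, H = 55, q = 3.8)
  r <- seq(0, 75, length.out = 200)
  prof <- structure(list(r = r, z = (r / 75)^3.8 * 55, H_obs = 55,
                         rim_radius = 75, units = "mm"),
                    class = "cross_section_profile")
  rep <- fit_model_to_profile(prof, mode = "free")
  expect_lt(abs(rep$bowl$R - 75) / 75, 1e-3)
  expect_lt(abs(rep$bowl$H - 55) / 55, 1e-3)
  expect_lt(abs(rep$bowl$q - 3.8) / 3.8, 1e-3)
  expect_lt(rep$mae, 1e-6)
  expect_equal(rep$relative_mae, rep$mae / rep$bowl$H * 100)
  expect_equal(rep$relative_rmse, rep$rmse / rep$bowl$H * 100)
  expect_gte(rep$rmse, rep$mae)
})

test_that("fixed-RH fitting uses hand measurements and fits only q", {
  b <- bowl_model(R = 60.5, H = 52, q = 3.3)
  r <- seq(0, 60.5, length.out = 150)
  prof <- structure(list(r = r, z = (r / 60.5)^3.3 * 52, H_obs = 52,
                         rim_radius = 60.5, units = "mm"),
                    class = "cross_section_profile")
  rep <- fit_model_to_profile(prof, mode = "fixed_RH", R = 60.5, H = 52)
  expect_equal(rep$bowl$R, 60.5)
  expect_equal(rep$bowl$H, 52)
  expect_lt(abs(rep$bowl$q - 3.3), 1e-3)
  expect_error(fit_model_to_profile(prof, mode = "fixed_RH"), "requires")
})

test_that("trapezoid-profile bowls fit the power-law model poorly", {
  # power-law-like synthetic bowls with scanner-like jitter stay accurate
  set.seed(44)
  rel_rmse <- numeric(0)
  specs <- list(c(60, 30, 3), c(80, 45, 5), c(110, 60, 8), c(50, 55, 6),
                c(70, 40, 2.5), c(95, 52, 7), c(65, 35, 4), c(85, 70, 9),
                c(120, 48, 3.5), c(75, 60, 5.5))
  for (sp in specs) {
    b <- bowl_model(R = sp[1], H = sp[2], q = sp[3])
    cloud <- synthesize_bowl_cloud(b, n = 15000, noise_sd = 0.3)
    prof <- extract_cross_section(cloud, slab_halfwidth = 2)
    rep <- fit_model_to_profile(prof, mode = "free")
    rel_rmse <- c(rel_rmse, rep$relative_rmse)
  }
  expect_true(all(rel_rmse > 0.3 & rel_rmse < 3.0))
  # a trapezoid cross-section (flat floor, straight sloped wall) is the
  # known failure mode: relative RMSE must be clearly larger
  r <- seq(0, 80, length.out = 400)
  z_trap <- pmax(0, (r - 40) / 40) * 55
  prof_t <- structure(list(r = r, z = z_trap, H_obs = 55, rim_radius = 80,
                           units = "mm"),
                      class = "cross_section_profile")
  rep_t <- fit_model_to_profile(prof_t, mode = "free")
  expect_gt(rep_t$relative_rmse, 3.0)            # outside the good band
  expect_gt(rep_t$relative_rmse, 2 * mean(rel_rmse))
})

test_that("inch-flagged profiles report errors in inches", {
  b <- bowl_model(R = 59.944, H = 59.944, q = 4)   # 2.36 in
  r_in <- seq(0, 2.36, length.out = 120)
  z_in <- (r_in / 2.36)^4 * 2.36
  prof <- structure(list(r = r_in, z = z_in + 0.01, H_obs = 2.36,
                         rim_radius = 2.36, units = "inches"),
                    class = "cross_section_profile")
  rep <- fit_model_to_profile(prof, mode = "fixed_RH", R = 2.36, H = 2.36)
  expect_equal(rep$bowl$R, 2.36 * 25.4)            # model stays in mm
  expect_lt(rep$mae, 0.02)                         # reported in inches
  expect_equal(rep$units, "inches")
})
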