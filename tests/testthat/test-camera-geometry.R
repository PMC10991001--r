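test_that("pinhole projection and undistortion are mutual inverses", {
  cal <- test_calib()
  expect_equal(unname(project_points(c(0, 0, 600), cal)[1, ]), c(960, 540))
  expect_equal(unname(project_points(c(60, 0, 600), cal)[1, ]), c(1060, 540))
  expect_error(project_points(c(0, 0, -10), cal), "behind camera")

  expect_equal(unname(undistort_points(c(1060, 540), cal)[1, ]), c(0.1, 0))

  # principal point maps to (0, 0) whatever the coefficients
  cal_d <- test_calib(dist = c(-0.1, 0.05, 0.001, -0.002, 0.01))
  expect_equal(unname(undistort_points(c(960, 540), cal_d)[1, ]), c(0, 0))

  # round trip distort(undistort(p)) == p within 1e-6 px on pixels that are
  # images of actual scene points (observed pixels are feasible by
  # construction)
  for (k1 in c(-0.3, -0.1, 0.1, 0.3)) {
    cal_k <- test_calib(dist = c(k1, 0.02, 0.001, -0.001, 0))
    set.seed(7)
    pts <- cbind(runif(50, -0.6, 0.6), runif(50, -0.4, 0.4), 1) * 600
    px <- project_points(pts, cal_k)
    nrm <- undistort_points(px, cal_k)
    back <- project_points(cbind(nrm * 600, 600), cal_k)
    expect_lt(max(abs(back - px)), 1e-6)
    expect_lt(max(abs(nrm - pts[, 1:2] / 600)), 1e-9)
  }
})

test_that("homography estimation inverts known ground-truth transforms", {
  # pure scale 2 plus shift (500, 500)
  H0 <- rbind(c(2, 0, 500), c(0, 2, 500), c(0, 0, 1))
  src <- expand.grid(x = c(-100, -30, 40, 120), y = c(-90, 0, 80, 150))
  src <- as.matrix(src)
  dst <- apply_homography(H0, src)
  H <- estimate_homography(src, dst)
  expect_equal(unname(apply_homography(H, c(10, 20))[1, ]), c(520, 540),
               tolerance = 1e-9)
  expect_lt(attr(H, "residual_px"), 1e-8)

  # identity correspondences give the identity map
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 100
  Hi <- estimate_homography(sq, sq)
  expect_equal(apply_homography(Hi, c(37, -12))[1, ], c(37, -12),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(estimate_homography(sq[1:3, ], sq[1:3, ]), ">= 4")
  collinear <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_homography(collinear, collinear), "degenerate")
})

test_that("planar pose recovery matches forward-constructed cameras", {
  cal <- test_calib()
  # fronto-parallel, axes aligned, 600 mm out
  H <- true_homography(diag(3), c(0, 0, -600), cal)
  pose <- pose_from_homography(H, cal)
  expect_equal(pose$camera_position_poster, c(0, 0, -600), tolerance = 1e-9)
  expect_equal(pose$perpendicular_distance, 600)

  # laterally translated camera
  H <- true_homography(diag(3), c(100, 0, -600), cal)
  pose <- pose_from_homography(H, cal)
  expect_equal(pose$perpendicular_distance, 600, tolerance = 1e-9)
  expect_equal(pose$euclidean_distance_to_origin, sqrt(100^2 + 600^2))
  expect_equal(round(pose$euclidean_distance_to_origin, 2), 608.28)

  # 30 deg yaw recovered to within 0.01 deg
  R <- rot_y(30)
  H <- true_homography(R, c(0, 0, -600), cal)
  pose <- pose_from_homography(H, cal)
  rot_err <- acos(pmin(1, (sum(diag(t(R) %*% pose$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(rot_err, 0.01)
})

test_that("homography + pose invert the forward projection over random poses", {
  cal <- test_calib()
  poster <- default_poster()
  corners <- do.call(rbind, lapply(poster$markers, marker_corners_mm))
  set.seed(11)
  for (i in 1:40) {
    gt <- random_pose()
    Ht <- true_homography(gt$R, gt$eye, cal)
    px <- apply_homography(Ht, corners)
    H <- estimate_homography(corners, px)
    held_out <- c(77.7, -33.3)
    expect_lt(max(abs(apply_homography(H, held_out) -
                        apply_homography(Ht, held_out))), 1e-6)
    pose <- pose_from_homography(H, cal)
    expect_lt(max(abs(pose$camera_position_poster - gt$eye)), 0.1)
    rot_err <- acos(pmin(1, (sum(diag(t(gt$R) %*% pose$rotation)) - 1) / 2)) * 180 / pi
    expect_lt(rot_err, 0.01)
  }
})

test_that("angle_between and Fick decomposition obey their conventions", {
  expect_equal(angle_between(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(angle_between(c(0, 0, 1), c(tan(10 * pi / 180), 0, 1)), 10)
  expect_equal(angle_between(c(0, 0, 1), c(0, 0, -1)), 180)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero")
  # symmetry and scale invariance
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(angle_between(a, b), angle_between(b, a))
    expect_equal(angle_between(3.7 * a, 0.2 * b), angle_between(a, b))
  }

  expect_equal(unname(direction_to_fick(c(0, 0, 1))), c(0, 0))
  expect_equal(unname(direction_to_fick(c(1, 0, 1))), c(45, 0))
  # y points down, so -y is up: positive elevation
  expect_equal(unname(direction_to_fick(c(0, -1, 1))), c(0, 45))
  expect_error(direction_to_fick(c(0, 0, 0)), "zero")
})

test_that("calibration JSON round trips", {
  cal <- test_calib(dist = c(-0.2, 0.04, 0.001, -0.0005, 0.002))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_calibration(cal, f)
  cal2 <- load_calibration(f)
  expect_equal(cal2$dist, cal$dist)
  expect_equal(cal2$fx, cal$fx)
  expect_equal(cal2$width, cal$width)
})
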