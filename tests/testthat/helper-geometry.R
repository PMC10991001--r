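# elementary rotations (poster -> camera)
rot_x <- function(deg) {
  t <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
}
rot_y <- function(deg) {
  t <- deg * pi / 180
  rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
}
rot_z <- function(deg) {
  t <- deg * pi / 180
  rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
}

test_calib <- function(dist = rep(0, 5)) {
  camera_calibration(1000, 1000, 960, 540, dist)
}

# forward-construct the exact homography K [r1 r2 t] for a planar pose
true_homography <- function(R, eye, calib) {
  K <- matrix(c(calib$fx, 0, 0, 0, calib$fy, 0, calib$cx, calib$cy, 1), 3, 3)
  t <- as.numeric(-R %*% eye)
  H <- K %*% cbind(R[, 1], R[, 2], t)
  H / H[3, 3]
}

# draw a random camera pose that keeps the default poster fully in front
random_pose <- function() {
  repeat {
    R <- rot_z(runif(1, -30, 30)) %*% rot_x(runif(1, -45, 45)) %*%
      rot_y(runif(1, -45, 45))
    eye <- c(runif(1, -200, 200), runif(1, -200, 200), runif(1, -1000, -400))
    corners <- rbind(c(-180, -180, 0), c(180, -180, 0), c(180, 180, 0),
                     c(-180, 180, 0), c(0, 0, 0))
    pc <- t(R %*% (t(corners) - eye))
    if (all(pc[, 3] > 100)) return(list(R = R, eye = eye))
  }
}

# minimal poster_gaze_series for directly scripted sample positions
make_series <- function(x_mm, y_mm, t_ms = (seq_along(x_mm) - 1) * 20,
                        eye = c(0, 0, -600), valid = rep(TRUE, length(x_mm)),
                        gaze_px_x = rep(NA_real_, length(x_mm)),
                        gaze_px_y = rep(NA_real_, length(x_mm)),
                        mode = "fixed_distance") {
  df <- data.frame(
    timestamp_ms = t_ms, frame_idx = seq_along(x_mm) - 1L,
    gaze_x_px = gaze_px_x, gaze_y_px = gaze_px_y,
    poster_x_mm = ifelse(valid, x_mm, NA_real_),
    poster_y_mm = ifelse(valid, y_mm, NA_real_),
    eye_x_mm = ifelse(valid, eye[1], NA_real_),
    eye_y_mm = ifelse(valid, eye[2], NA_real_),
    eye_z_mm = ifelse(valid, eye[3], NA_real_),
    valid = valid,
    reason = ifelse(valid, "ok", "gaze-missing"),
    stringsAsFactors = FALSE
  )
  structure(df, mode = mode, assumed_eye = eye, calibration = NULL,
            class = c("poster_gaze_series", "data.frame"))
}

# scripted multi-dwell scanpath on the poster plane (angular dwell noise)
make_scanpath_series <- function(targets_xy, dwell_n = 50, rate_hz = 50,
                                 sigma_deg = 0, eye = c(0, 0, -600),
                                 seed = 42) {
  set.seed(seed)
  n <- dwell_n * nrow(targets_xy)
  x <- rep(targets_xy[, 1], each = dwell_n)
  y <- rep(targets_xy[, 2], each = dwell_n)
  if (sigma_deg > 0) {
    x <- x + abs(eye[3]) * tan(rnorm(n, 0, sigma_deg) * pi / 180)
    y <- y + abs(eye[3]) * tan(rnorm(n, 0, sigma_deg) * pi / 180)
  }
  make_series(x, y, t_ms = (seq_len(n) - 1) * 1000 / rate_hz, eye = eye)
}
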