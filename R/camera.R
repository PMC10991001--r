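#' Scene-camera calibration
#'
#' Pinhole intrinsics plus Brown-Conrady distortion for the forward-facing
#' scene camera of a pair of eye-tracking glasses. The five distortion
#' coefficients follow the usual (k1, k2, p1, p2, k3) layout: three radial
#' terms and two tangential.
#'
#' @param fx,fy Focal lengths, px (> 0).
#' @param cx,cy Principal point, px.
#' @param dist Numeric vector of 5 distortion coefficients; default all zero.
#' @param width,height Sensor resolution, px.
#' @return An object of class `camera_calibration`.
#' @export
camera_calibration <- function(fx, fy, cx, cy, dist = rep(0, 5),
                               width = 1920, height = 1080) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  dist <- as.numeric(dist)
  if (length(dist) < 5) dist <- c(dist, rep(0, 5 - length(dist)))
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy), cx = as.numeric(cx),
         cy = as.numeric(cy), dist = dist[1:5],
         width = as.integer(width), height = as.integer(height)),
    class = "camera_calibration"
  )
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration> %dx%d px, f = (%.1f, %.1f), c = (%.1f, %.1f)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

# intrinsics matrix
camera_K <- function(calib) {
  matrix(c(calib$fx, 0, 0, 0, calib$fy, 0, calib$cx, calib$cy, 1), 3, 3)
}

# Brown-Conrady forward distortion of normalized coordinates (n x 2)
distort_normalized <- function(xy, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x * x + y * y
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
  yd <- y * radial + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
  cbind(xd, yd)
}

#' Project camera-frame points to pixels
#'
#' Standard pinhole projection with Brown-Conrady distortion. Points must be
#' in front of the camera (z > 0).
#'
#' @param p_camera Points in the camera frame, mm: a 3-vector or n x 3 matrix.
#' @param calib A `camera_calibration`.
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(p_camera, calib) {
  p <- if (is.null(dim(p_camera))) matrix(p_camera, 1) else as.matrix(p_camera)
  stopifnot(ncol(p) == 3)
  if (any(p[, 3] <= 0)) stop("point behind camera (z <= 0)", call. = FALSE)
  xy <- cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
  d <- distort_normalized(xy, calib$dist)
  cbind(x = calib$fx * d[, 1] + calib$cx, y = calib$fy * d[, 2] + calib$cy)
}

#' Undistort pixels to normalized image coordinates
#'
#' Inverts the distortion model by Newton iteration on the normalized
#' coordinates, then removes the intrinsics. For points inside the frame and
#' |k1| up to about 0.3 the round trip `project(undistort(p))` is accurate
#' to better than 1e-6 px.
#'
#' @param px Pixel coordinates: 2-vector or n x 2 matrix.
#' @param calib A `camera_calibration`.
#' @param max_iter Iteration cap (default 50).
#' @return n x 2 matrix of normalized (distortion-free pinhole) coordinates.
#' @export
undistort_points <- function(px, calib, max_iter = 50) {
  p <- if (is.null(dim(px))) matrix(px, 1) else as.matrix(px)
  stopifnot(ncol(p) == 2)
  x0 <- (p[, 1] - calib$cx) / calib$fx
  y0 <- (p[, 2] - calib$cy) / calib$fy
  x <- x0; y <- y0
  k1 <- calib$dist[1]; k2 <- calib$dist[2]
  p1 <- calib$dist[3]; p2 <- calib$dist[4]; k3 <- calib$dist[5]
  for (i in seq_len(max_iter)) {
    r2 <- x * x + y * y
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    D <- k1 + 2 * k2 * r2 + 3 * k3 * r2^2
    fx_ <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x * x) - x0
    fy_ <- y * radial + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y - y0
    if (max(abs(fx_), abs(fy_)) < 1e-14) break
    j11 <- radial + 2 * x * x * D + 2 * p1 * y + 6 * p2 * x
    j12 <- 2 * x * y * D + 2 * p1 * x + 2 * p2 * y
    j21 <- 2 * x * y * D + 2 * p1 * x + 2 * p2 * y
    j22 <- radial + 2 * y * y * D + 6 * p1 * y + 2 * p2 * x
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-15] <- 1e-15
    x <- x - (j22 * fx_ - j12 * fy_) / det
    y <- y - (-j21 * fx_ + j11 * fy_) / det
  }
  cbind(x = x, y = y)
}

# undistorted "ideal pinhole" pixel coordinates (distortion removed,
# intrinsics re-applied); identity when dist == 0
ideal_pixels <- function(px, calib) {
  n <- undistort_points(px, calib)
  cbind(calib$fx * n[, 1] + calib$cx, calib$fy * n[, 2] + calib$cy)
}

#' Save / load a camera calibration as JSON
#'
#' Keys: `fx, fy, cx, cy, dist` (length 5), `width, height`.
#'
#' @param calib A `camera_calibration`.
#' @param path File path.
#' @return `save_calibration`: `path` invisibly. `load_calibration`: a
#'   `camera_calibration`.
#' @export
save_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_calibration(o$fx, o$fy, o$cx, o$cy, o$dist, o$width, o$height)
}
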