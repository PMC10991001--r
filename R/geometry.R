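#' Angle between two 3-vectors
#'
#' Arc-cosine of the clamped normalized dot product, in degrees, range
#' \[0, 180\]. Symmetric and invariant to positive rescaling of either
#' argument.
#'
#' @param v1,v2 Nonzero 3-vectors.
#' @return Angle in degrees.
#' @export
angle_between <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector", call. = FALSE)
  d <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Fick-angle decomposition of a direction
#'
#' Azimuth = atan2(x, z), positive rightward; elevation =
#' atan2(-y, sqrt(x^2 + z^2)), positive upward (the frame has y pointing
#' down). The direction must point forward (z > 0 convention, toward the
#' poster).
#'
#' @param d Nonzero 3-vector or n x 3 matrix of directions.
#' @return `c(azimuth, elevation)` in degrees, or an n x 2 matrix.
#' @export
direction_to_fick <- function(d) {
  m <- if (is.null(dim(d))) matrix(d, 1) else as.matrix(d)
  if (any(rowSums(m^2) == 0)) stop("zero vector", call. = FALSE)
  az <- atan2(m[, 1], m[, 3]) * 180 / pi
  el <- atan2(-m[, 2], sqrt(m[, 1]^2 + m[, 3]^2)) * 180 / pi
  out <- cbind(azimuth = az, elevation = el)
  if (is.null(dim(d))) out[1, ] else out
}

# inverse of direction_to_fick (unit direction from degrees)
fick_to_direction <- function(az_deg, el_deg) {
  az <- az_deg * pi / 180; el <- el_deg * pi / 180
  cbind(cos(el) * sin(az), -sin(el), cos(el) * cos(az))
}

#' Estimate a plane-to-image homography
#'
#' Normalized direct linear transform (DLT): both point sets are translated
#' to their centroid and scaled to mean distance sqrt(2) before solving the
#' 2n x 9 system by SVD. Needs at least 4 non-collinear correspondences; a
#' single detected marker supplies its 4 corners. On noiseless input the
#' recovered map reproduces held-out plane points to well below 1e-6 px.
#'
#' @param src n x 2 matrix of poster-plane points, mm.
#' @param dst n x 2 matrix of corresponding image points, px.
#' @return An object of class `homography`: the 3 x 3 matrix (normalized so
#'   `H[3,3] == 1` when nonzero) with the mean reprojection residual (px)
#'   attached as attribute `residual_px`.
#' @export
estimate_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4 || nrow(dst) != nrow(src)) {
    stop("need >= 4 point correspondences", call. = FALSE)
  }
  norm_T <- function(pts) {
    ctr <- colMeans(pts)
    d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  }
  Ts <- norm_T(src); Td <- norm_T(dst)
  hs <- cbind(src, 1) %*% t(Ts)
  hd <- cbind(dst, 1) %*% t(Td)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- hs[i, ]; u <- hd[i, 1]; v <- hd[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  if (sv$d[8] < 1e-10 * max(sv$d)) {
    stop("degenerate point configuration for homography", call. = FALSE)
  }
  H <- solve(Td) %*% matrix(h, 3, 3, byrow = TRUE) %*% Ts
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  proj <- apply_homography(H, src)
  res <- mean(sqrt(rowSums((proj - dst)^2)))
  structure(H, residual_px = res, class = c("homography", "matrix", "array"))
}

#' Apply a homography to 2-D points
#'
#' @param H 3 x 3 homography (or its inverse, for image-to-plane mapping).
#' @param pts 2-vector or n x 2 matrix.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  p <- if (is.null(dim(pts))) matrix(pts, 1) else as.matrix(pts)
  q <- cbind(p, 1) %*% t(unclass(H))
  cbind(q[, 1] / q[, 3], q[, 2] / q[, 3])
}

#' Recover planar pose from a homography
#'
#' Decomposes K^-1 H into \[r1 r2 t\]: the scale is fixed by the mean norm of
#' the first two columns, the sign by requiring the plane in front of the
#' camera (t_z > 0), r3 = r1 x r2, and the rotation is projected to the
#' nearest orthonormal matrix by SVD. The homography must have been estimated
#' against distortion-free (ideal pinhole) image coordinates.
#'
#' @param H A `homography` mapping poster mm to ideal pixels.
#' @param calib A `camera_calibration`.
#' @return An object of class `planar_pose`: `rotation` (3 x 3, poster to
#'   camera), `translation` (mm), `camera_position_poster` (= -R't, mm),
#'   `perpendicular_distance` (|z| of the camera position, mm) and
#'   `euclidean_distance_to_origin` (mm).
#' @export
pose_from_homography <- function(H, calib) {
  M <- solve(camera_K(calib)) %*% unclass(H)
  n1 <- sqrt(sum(M[, 1]^2)); n2 <- sqrt(sum(M[, 2]^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("singular homography", call. = FALSE)
  lambda <- 2 / (n1 + n2)
  M <- M * lambda
  if (M[3, 3] < 0) M <- -M  # plane must be in front of the camera
  r1 <- M[, 1]; r2 <- M[, 2]; t <- M[, 3]
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  Rraw <- cbind(r1, r2, r3)
  sv <- svd(Rraw)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  cam_pos <- as.numeric(-t(R) %*% t)
  structure(
    list(rotation = R, translation = t,
         camera_position_poster = cam_pos,
         perpendicular_distance = abs(cam_pos[3]),
         euclidean_distance_to_origin = sqrt(sum(cam_pos^2))),
    class = "planar_pose"
  )
}

#' @export
print.planar_pose <- function(x, ...) {
  cat(sprintf("<planar_pose> camera at (%.1f, %.1f, %.1f) mm, perpendicular distance %.1f mm\n",
              x$camera_position_poster[1], x$camera_position_poster[2],
              x$camera_position_poster[3], x$perpendicular_distance))
  invisible(x)
}
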