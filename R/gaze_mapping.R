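#' Per-frame poster geometry from marker detections
#'
#' For every scene-video frame referenced by the gaze data, pools the corner
#' correspondences of all detected markers whose ids exist in the poster
#' specification and estimates one homography from poster millimetres to
#' image pixels (more corners give a stabler estimate than averaging
#' per-marker homographies). When a camera calibration is available the
#' corners are first undistorted to ideal pinhole pixels, and the planar
#' camera pose is additionally recovered from the homography. Frames with no
#' usable detections yield missing geometry with a reason, never silently.
#'
#' @param rec A `recording`.
#' @param poster A `poster_spec`.
#' @return An object of class `frame_geometries`: per frame, the frame index,
#'   a representative timestamp (ms, first gaze sample on the frame), the
#'   homography (poster mm to \[ideal\] px) and its inverse, the `planar_pose`
#'   (calibrated recordings only), and the number of markers used.
#' @export
frame_geometries <- function(rec, poster) {
  frames <- sort(unique(rec$gaze$frame_idx))
  ts <- vapply(frames, function(f) {
    rec$gaze$timestamp_ms[match(f, rec$gaze$frame_idx)]
  }, numeric(1))
  known_ids <- vapply(poster$markers, `[[`, integer(1), "id")
  corners_mm <- lapply(poster$markers, marker_corners_mm)
  names(corners_mm) <- as.character(known_ids)
  unknown <- setdiff(unique(rec$markers$marker_id), known_ids)
  if (length(unknown)) {
    warning("ignoring detections of marker id(s) not in poster: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  calib <- rec$calibration
  entries <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    obs <- rec$markers[rec$markers$frame_idx == frames[i] &
                         rec$markers$marker_id %in% known_ids, , drop = FALSE]
    if (nrow(obs) == 0) {
      entries[[i]] <- list(frame_idx = frames[i], timestamp_ms = ts[i],
                           homography = NULL, h_inverse = NULL, pose = NULL,
                           n_markers_used = 0L, reason = "no-markers")
      next
    }
    src <- do.call(rbind, corners_mm[as.character(obs$marker_id)])
    dst <- do.call(rbind, lapply(seq_len(nrow(obs)), function(j) {
      matrix(as.numeric(obs[j, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")]),
             4, 2, byrow = TRUE)
    }))
    if (!is.null(calib)) dst <- ideal_pixels(dst, calib)
    geom <- tryCatch({
      H <- estimate_homography(src, dst)
      pose <- if (!is.null(calib)) pose_from_homography(H, calib) else NULL
      list(frame_idx = frames[i], timestamp_ms = ts[i], homography = H,
           h_inverse = solve(unclass(H)), pose = pose,
           n_markers_used = nrow(obs), reason = "ok")
    }, error = function(e) {
      list(frame_idx = frames[i], timestamp_ms = ts[i], homography = NULL,
           h_inverse = NULL, pose = NULL, n_markers_used = nrow(obs),
           reason = conditionMessage(e))
    })
    entries[[i]] <- geom
  }
  structure(list(frames = frames, entries = entries),
            class = "frame_geometries")
}

#' Fill short gaps in per-frame geometry
#'
#' Marker detection can drop out for a frame or two (motion blur, occlusion).
#' Frames without geometry borrow the nearest-in-time valid geometry when the
#' time difference is at most `max_gap_ms`; longer dropouts stay missing.
#' Nearest-neighbour substitution is used rather than interpolating matrix
#' entries, which is not projectively sound.
#'
#' @param geoms A `frame_geometries`.
#' @param max_gap_ms Largest gap to bridge, ms (default 100).
#' @return The `frame_geometries` with short gaps filled.
#' @export
fill_missing_geometry <- function(geoms, max_gap_ms = 100) {
  has <- vapply(geoms$entries, function(e) !is.null(e$homography), logical(1))
  if (all(has) || !any(has)) return(geoms)
  ts <- vapply(geoms$entries, `[[`, numeric(1), "timestamp_ms")
  valid_ts <- ts[has]
  valid_idx <- which(has)
  for (i in which(!has)) {
    j <- which.min(abs(valid_ts - ts[i]))
    if (abs(valid_ts[j] - ts[i]) <= max_gap_ms) {
      src <- geoms$entries[[valid_idx[j]]]
      geoms$entries[[i]]$homography <- src$homography
      geoms$entries[[i]]$h_inverse <- src$h_inverse
      geoms$entries[[i]]$pose <- src$pose
      geoms$entries[[i]]$reason <- "gap-filled"
    }
  }
  geoms
}

#' Map gaze samples to the poster plane
#'
#' Transforms each gaze sample from scene-video pixels to millimetres on the
#' poster and attaches a per-sample eye position in the poster frame. In
#' `"pose_estimated"` mode (requires a calibration) the gaze pixel is
#' undistorted before applying the frame's inverse homography, and the eye
#' position is that frame's recovered camera position; in `"fixed_distance"`
#' mode the raw-pixel homography is applied directly and every eye position
#' is the assumed `(0, 0, -assumed_distance)` — the participant is taken to
#' stand exactly in front of the poster centre at a perpendicular distance.
#' The eye is equated with the scene-camera optical centre.
#'
#' @param rec A `recording` (typically an episode slice).
#' @param geoms `frame_geometries` for `rec` (computed if omitted).
#' @param poster A `poster_spec`.
#' @param mode `"pose_estimated"` or `"fixed_distance"`.
#' @param assumed_distance Assumed perpendicular viewing distance, mm
#'   (default the poster's).
#' @return An object of class `poster_gaze_series`: a data.frame with one row
#'   per gaze sample (`timestamp_ms`, `frame_idx`, `gaze_x_px`, `gaze_y_px`,
#'   `poster_x_mm`, `poster_y_mm`, `eye_x_mm`, `eye_y_mm`, `eye_z_mm`,
#'   `valid`, `reason`), with the mode, assumed eye and calibration attached
#'   as attributes.
#' @export
map_gaze <- function(rec, geoms = NULL, poster = default_poster(),
                     mode = c("pose_estimated", "fixed_distance"),
                     assumed_distance = poster$assumed_distance) {
  mode <- match.arg(mode)
  if (mode == "pose_estimated" && is.null(rec$calibration)) {
    stop("pose_estimated mode requires a camera calibration", call. = FALSE)
  }
  if (is.null(geoms)) geoms <- frame_geometries(rec, poster)
  g <- rec$gaze
  n <- nrow(g)
  assumed_eye <- c(0, 0, -assumed_distance)
  out <- data.frame(
    timestamp_ms = g$timestamp_ms, frame_idx = g$frame_idx,
    gaze_x_px = g$gaze_x_px, gaze_y_px = g$gaze_y_px,
    poster_x_mm = NA_real_, poster_y_mm = NA_real_,
    eye_x_mm = NA_real_, eye_y_mm = NA_real_, eye_z_mm = NA_real_,
    valid = FALSE, reason = "gaze-missing", stringsAsFactors = FALSE
  )
  idx <- match(g$frame_idx, geoms$frames)
  calib <- rec$calibration
  for (i in seq_len(n)) {
    if (is.na(g$gaze_x_px[i])) next
    e <- if (!is.na(idx[i])) geoms$entries[[idx[i]]] else NULL
    if (is.null(e) || is.null(e$h_inverse)) {
      out$reason[i] <- "no-markers"
      next
    }
    px <- c(g$gaze_x_px[i], g$gaze_y_px[i])
    if (!is.null(calib)) px <- ideal_pixels(matrix(px, 1), calib)[1, ]
    pmm <- apply_homography(e$h_inverse, px)[1, ]
    eye <- if (mode == "pose_estimated") {
      e$pose$camera_position_poster
    } else assumed_eye
    out$poster_x_mm[i] <- pmm[1]; out$poster_y_mm[i] <- pmm[2]
    out$eye_x_mm[i] <- eye[1]; out$eye_y_mm[i] <- eye[2]; out$eye_z_mm[i] <- eye[3]
    out$valid[i] <- TRUE; out$reason[i] <- "ok"
  }
  structure(out, mode = mode, assumed_eye = assumed_eye, calibration = calib,
            class = c("poster_gaze_series", "data.frame"))
}

#' Export a mapped gaze series to CSV
#'
#' @param series A `poster_gaze_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
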