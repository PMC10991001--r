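#' Construct a recording
#'
#' Vendor-neutral container for one wearable eye-tracker recording: gaze
#' samples in scene-video pixel coordinates, per-frame fiducial-marker corner
#' detections, validation-episode annotations, and an optional scene-camera
#' calibration. Pixel origin is the top-left of the scene frame, x right,
#' y down; timestamps are milliseconds; episodes are half-open
#' `[start, end)` intervals.
#'
#' @param gaze data.frame with columns `timestamp_ms`, `frame_idx`,
#'   `gaze_x_px`, `gaze_y_px` (NA = missing sample). Timestamps must be
#'   strictly increasing.
#' @param markers data.frame with columns `frame_idx`, `marker_id`,
#'   `x1, y1, ..., x4, y4` (corner order: top-left, top-right, bottom-right,
#'   bottom-left).
#' @param episodes data.frame with columns `start_ms`, `end_ms`, `label`;
#'   episodes must not overlap.
#' @param calibration Optional `camera_calibration`.
#' @param meta Optional named list of device / participant labels.
#' @return An object of class `recording`. The median sampling rate (Hz) is
#'   derived from the gaze timestamps and stored as `$sampling_rate`.
#' @export
recording <- function(gaze, markers = empty_markers(), episodes = empty_episodes(),
                      calibration = NULL, meta = list()) {
  gaze <- as.data.frame(gaze)
  markers <- as.data.frame(markers)
  episodes <- as.data.frame(episodes)
  rownames(gaze) <- rownames(markers) <- rownames(episodes) <- NULL
  need_g <- c("timestamp_ms", "frame_idx", "gaze_x_px", "gaze_y_px")
  if (!all(need_g %in% names(gaze))) {
    stop("gaze must have columns ", paste(need_g, collapse = ", "), call. = FALSE)
  }
  dt <- diff(gaze$timestamp_ms)
  if (length(dt) && any(dt <= 0)) {
    stop("gaze timestamps not strictly increasing at row ",
         which(dt <= 0)[1] + 1L, call. = FALSE)
  }
  # one coordinate missing means the sample is missing
  part <- xor(is.na(gaze$gaze_x_px), is.na(gaze$gaze_y_px))
  if (any(part)) {
    gaze$gaze_x_px[part] <- NA_real_
    gaze$gaze_y_px[part] <- NA_real_
  }
  if (nrow(episodes) > 1) {
    ep <- episodes[order(episodes$start_ms), ]
    ov <- which(ep$end_ms[-nrow(ep)] > ep$start_ms[-1])
    if (length(ov)) {
      stop("episodes overlap at row ", ov[1] + 1L, call. = FALSE)
    }
  }
  if (nrow(episodes) && any(episodes$start_ms >= episodes$end_ms)) {
    stop("episode with start >= end at row ",
         which(episodes$start_ms >= episodes$end_ms)[1], call. = FALSE)
  }
  rate <- if (length(dt)) 1000 / stats::median(dt) else NA_real_
  structure(
    list(gaze = gaze, markers = markers, episodes = episodes,
         calibration = calibration, sampling_rate = rate, meta = meta),
    class = "recording"
  )
}

empty_markers <- function() {
  data.frame(frame_idx = integer(), marker_id = integer(),
             x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             x3 = numeric(), y3 = numeric(), x4 = numeric(), y4 = numeric())
}

empty_episodes <- function() {
  data.frame(start_ms = numeric(), end_ms = numeric(), label = character())
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d gaze samples @ %.1f Hz, %d marker detections, %d episode(s)%s\n",
              nrow(x$gaze), x$sampling_rate, nrow(x$markers), nrow(x$episodes),
              if (is.null(x$calibration)) ", no calibration" else ", calibrated"))
  invisible(x)
}

#' Read / write a recording directory
#'
#' The interchange layout is a directory holding `gaze.csv`
#' (timestamp_ms, frame_idx, gaze_x_px, gaze_y_px; empty cells = missing),
#' `markers.csv` (frame_idx, marker_id, x1..y4), `episodes.csv`
#' (start_ms, end_ms, label) and optionally `calibration.json`. The round
#' trip `read_recording(write_recording(rec, d))` is lossless; missing gaze
#' is never silently turned into zeros.
#'
#' @param dir_path Directory path.
#' @return `read_recording`: a `recording`. `write_recording`: `dir_path`,
#'   invisibly.
#' @export
read_recording <- function(dir_path) {
  gp <- file.path(dir_path, "gaze.csv")
  if (!file.exists(gp)) stop("no gaze.csv in ", dir_path, call. = FALSE)
  gaze <- utils::read.csv(gp)
  mp <- file.path(dir_path, "markers.csv")
  markers <- if (file.exists(mp)) utils::read.csv(mp) else empty_markers()
  ep <- file.path(dir_path, "episodes.csv")
  episodes <- if (file.exists(ep)) utils::read.csv(ep) else empty_episodes()
  cp <- file.path(dir_path, "calibration.json")
  calib <- if (file.exists(cp)) load_calibration(cp) else NULL
  meta <- list()
  mt <- file.path(dir_path, "meta.json")
  if (file.exists(mt)) meta <- jsonlite::read_json(mt, simplifyVector = TRUE)
  recording(gaze, markers, episodes, calib, meta)
}

#' @rdname read_recording
#' @param rec A `recording`.
#' @export
write_recording <- function(rec, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rec$gaze, file.path(dir_path, "gaze.csv"), row.names = FALSE)
  utils::write.csv(rec$markers, file.path(dir_path, "markers.csv"), row.names = FALSE)
  utils::write.csv(rec$episodes, file.path(dir_path, "episodes.csv"), row.names = FALSE)
  if (!is.null(rec$calibration)) {
    save_calibration(rec$calibration, file.path(dir_path, "calibration.json"))
  }
  if (length(rec$meta)) {
    jsonlite::write_json(rec$meta, file.path(dir_path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir_path)
}

#' Restrict a recording to one episode
#'
#' Keeps gaze samples with `start <= t < end` and the marker observations of
#' the frames those samples reference. An episode outside the recorded span
#' yields an (explicitly) empty recording, not an error, so that downstream
#' per-episode processing stays independent.
#'
#' @param rec A `recording`.
#' @param start_ms,end_ms Episode bounds, ms (half-open).
#' @return A `recording` restricted to the episode (episodes table reduced to
#'   this one episode).
#' @export
slice_episode <- function(rec, start_ms, end_ms) {
  keep <- rec$gaze$timestamp_ms >= start_ms & rec$gaze$timestamp_ms < end_ms
  gaze <- rec$gaze[keep, , drop = FALSE]
  frames <- unique(gaze$frame_idx)
  markers <- rec$markers[rec$markers$frame_idx %in% frames, , drop = FALSE]
  ep <- data.frame(start_ms = start_ms, end_ms = end_ms, label = "episode")
  out <- structure(
    list(gaze = gaze, markers = markers, episodes = ep,
         calibration = rec$calibration,
         sampling_rate = if (nrow(gaze) > 1)
           1000 / stats::median(diff(gaze$timestamp_ms)) else rec$sampling_rate,
         meta = rec$meta),
    class = "recording"
  )
  out
}

#' Data loss within an episode
#'
#' Percentage of gaze samples in the episode whose pixel coordinates are
#' missing. Invariant to timestamp offsets and to the sampling rate.
#'
#' @param rec A `recording`.
#' @param start_ms,end_ms Episode bounds, ms; default the recording's full
#'   span.
#' @return Percent in \[0, 100\], or `NA` if the episode holds no samples.
#' @export
data_loss <- function(rec, start_ms = -Inf, end_ms = Inf) {
  keep <- rec$gaze$timestamp_ms >= start_ms & rec$gaze$timestamp_ms < end_ms
  n <- sum(keep)
  if (n == 0) return(NA_real_)
  100 * sum(is.na(rec$gaze$gaze_x_px[keep])) / n
}
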