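#' Match classified fixations to fixation targets
#'
#' For each target, the nearest fixation in poster space that lasted at least
#' `min_dur_ms` is selected, under the constraint that no fixation serves
#' more than one target. All (target, eligible fixation) pairs are sorted by
#' ascending centroid-target distance and assigned greedily, skipping targets
#' and fixations already used; the assignment is injective and total over
#' `min(#targets, #eligible fixations)`. Unmatched targets are reported, not
#' imputed.
#'
#' @param fixations A `fixations` data.frame ([classify_fixations()]).
#' @param poster A `poster_spec`.
#' @param min_dur_ms Eligibility threshold on fixation duration, ms
#'   (default 50).
#' @return data.frame with one row per target: `target_id`, `fixation_row`
#'   (row index into `fixations`, `NA` if unmatched) and `distance_mm`.
#' @export
match_targets <- function(fixations, poster, min_dur_ms = 50) {
  tp <- target_positions(poster)
  out <- data.frame(target_id = tp[, "id"], fixation_row = NA_integer_,
                    distance_mm = NA_real_)
  eligible <- which(fixations$duration_ms >= min_dur_ms)
  if (!length(eligible) || nrow(fixations) == 0) return(out)
  pairs <- expand.grid(ti = seq_len(nrow(tp)), fi = eligible)
  pairs$d <- sqrt((tp[pairs$ti, "x"] - fixations$centroid_x_mm[pairs$fi])^2 +
                  (tp[pairs$ti, "y"] - fixations$centroid_y_mm[pairs$fi])^2)
  pairs <- pairs[order(pairs$d), ]
  used_f <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    ti <- pairs$ti[k]; fi <- pairs$fi[k]
    if (!is.na(out$fixation_row[ti]) || fi %in% used_f) next
    out$fixation_row[ti] <- fi
    out$distance_mm[ti] <- pairs$d[k]
    used_f <- c(used_f, fi)
  }
  out
}

#' Angular accuracy of a gaze position
#'
#' The angle between the vector from the eye to the gaze point on the poster
#' and the vector from the eye to the fixation target — the inaccuracy alpha,
#' in degrees.
#'
#' @param gaze_xy Gaze position on the poster plane, mm (2-vector).
#' @param target_xy Target position, mm (2-vector).
#' @param eye_pos Eye position in the poster frame, mm (3-vector, z < 0).
#' @return Degrees.
#' @export
accuracy_deg <- function(gaze_xy, target_xy, eye_pos) {
  angle_between(c(gaze_xy, 0) - eye_pos, c(target_xy, 0) - eye_pos)
}

#' Precision of the gaze samples within one matched fixation
#'
#' Per member sample, the angular offset to the target is expressed in Fick
#' angles: the azimuth/elevation of the direction from that sample's eye
#' position to the gaze point, minus those of the direction to the target.
#' RMS-S2S is the root mean square over successive sample pairs of the
#' squared azimuth and elevation increments; STD is the square root of the
#' summed population variances of azimuth and elevation offsets.
#'
#' @param series The (interpolated or raw) `poster_gaze_series`.
#' @param start_idx,end_idx Member sample range (rows of `series`).
#' @param target_xy Target position, mm.
#' @return `c(rms_s2s_deg, std_deg, n)`; precision values are `NA` with
#'   fewer than 2 valid member samples.
#' @export
precision_deg <- function(series, start_idx, end_idx, target_xy) {
  idx <- start_idx:end_idx
  idx <- idx[series$valid[idx] &
               !(if ("interpolated" %in% names(series)) series$interpolated[idx] else FALSE)]
  n <- length(idx)
  if (n < 2) return(c(rms_s2s_deg = NA_real_, std_deg = NA_real_, n = n))
  eye <- cbind(series$eye_x_mm[idx], series$eye_y_mm[idx], series$eye_z_mm[idx])
  gdir <- cbind(series$poster_x_mm[idx], series$poster_y_mm[idx], 0) - eye
  tdir <- cbind(target_xy[1], target_xy[2], 0)[rep(1, n), , drop = FALSE] - eye
  off <- direction_to_fick(gdir) - direction_to_fick(tdir)
  daz <- diff(off[, 1]); del <- diff(off[, 2])
  rms <- sqrt(mean(daz^2 + del^2))
  pvar <- function(x) mean((x - mean(x))^2)
  std <- sqrt(pvar(off[, 1]) + pvar(off[, 2]))
  c(rms_s2s_deg = rms, std_deg = std, n = n)
}

#' Gaze range across matched fixations
#'
#' Quantifies how much of the scene camera's field of view the gaze signal
#' covered during the validation: for each matched fixation, the mean gaze
#' pixel (scene-video frame) is undistorted and back-projected through the
#' intrinsics into a gaze direction in the camera frame; the horizontal and
#' vertical ranges are the max minus min azimuth and elevation across the
#' matched fixations. With a perfectly still head and eye movements only,
#' the ranges equal the angular size of the target grid; with head movements
#' toward each target they shrink toward zero.
#'
#' @param matches Output of [match_targets()].
#' @param fixations The `fixations` the matches refer to.
#' @param series The `poster_gaze_series` (carries the raw gaze pixels).
#' @param calib A `camera_calibration`.
#' @return `c(horizontal = deg, vertical = deg)`, `NA` with fewer than 2
#'   matched targets.
#' @export
gaze_range <- function(matches, fixations, series, calib) {
  rows <- matches$fixation_row[!is.na(matches$fixation_row)]
  if (length(rows) < 2 || is.null(calib)) {
    return(c(horizontal = NA_real_, vertical = NA_real_))
  }
  az <- el <- numeric(0)
  for (fi in rows) {
    idx <- fixations$start_idx[fi]:fixations$end_idx[fi]
    idx <- idx[!is.na(series$gaze_x_px[idx])]
    if (!length(idx)) next
    mean_px <- c(mean(series$gaze_x_px[idx]), mean(series$gaze_y_px[idx]))
    nrm <- undistort_points(mean_px, calib)[1, ]
    f <- direction_to_fick(c(nrm[1], nrm[2], 1))
    az <- c(az, f[1]); el <- c(el, f[2])
  }
  if (length(az) < 2) return(c(horizontal = NA_real_, vertical = NA_real_))
  c(horizontal = max(az) - min(az), vertical = max(el) - min(el))
}

#' Error introduced by assuming a fixed viewing position
#'
#' Ratio of the measures computed under an assumed fixed viewing distance to
#' those computed with the continuously estimated (physical) viewing
#' position, as a percentage: `accuracy_fixed / accuracy_physical * 100`,
#' and similarly for each precision measure. 100% means the assumption was
#' harmless.
#'
#' @param result_fixed,result_pose Per-target data.frames from
#'   [compute_data_quality()] run in `fixed_distance` and `pose_estimated`
#'   mode on the same episode.
#' @return data.frame per target: `accuracy_ratio_percent`,
#'   `rms_s2s_ratio_percent`, `std_ratio_percent` (`NA` where a denominator
#'   is zero or a target unmatched).
#' @export
fixed_distance_error_ratio <- function(result_fixed, result_pose) {
  stopifnot(identical(result_fixed$target_id, result_pose$target_id))
  ratio <- function(a, b) ifelse(!is.na(b) & b > 0, 100 * a / b, NA_real_)
  data.frame(
    target_id = result_fixed$target_id,
    accuracy_ratio_percent = ratio(result_fixed$accuracy_deg, result_pose$accuracy_deg),
    rms_s2s_ratio_percent = ratio(result_fixed$rms_s2s_deg, result_pose$rms_s2s_deg),
    std_ratio_percent = ratio(result_fixed$std_deg, result_pose$std_deg)
  )
}

#' Data quality of the validation episodes of a recording
#'
#' Runs the full chain on each validation episode: episode slicing, per-frame
#' marker geometry (with short-gap filling), gaze mapping to the poster,
#' fixation classification, nearest-fixation target matching (>= 50 ms rule),
#' and per-target accuracy and precision, plus episode-level data loss and
#' gaze range. In `pose_estimated` mode the eye position of a fixation is the
#' component-wise median of its member samples' recovered camera positions;
#' in `fixed_distance` mode it is `(0, 0, -assumed_distance)`.
#'
#' @param rec A `recording` with episode annotations (or pass `episodes` as a
#'   data.frame to override).
#' @param poster A `poster_spec`.
#' @param mode `"pose_estimated"` (requires calibration) or
#'   `"fixed_distance"`.
#' @param assumed_distance Assumed perpendicular viewing distance, mm.
#' @param params A `classifier_params`.
#' @param min_match_dur_ms Fixation eligibility threshold for matching, ms.
#' @param geometry_gap_ms Largest marker-dropout gap bridged per frame, ms.
#' @return A list of class `episode_dq`, one element per episode, each with
#'   `episode` (label, bounds), `targets` (per-target data.frame:
#'   `target_id`, `accuracy_deg`, `rms_s2s_deg`, `std_deg`, `n_samples`,
#'   `viewing_distance_mm`, `eye_x_mm`, `eye_y_mm`, `eye_z_mm`,
#'   `distance_mm`), `data_loss_percent`, `gaze_range_deg`, `mode`, and the
#'   intermediate `series`, `fixations`, `matches`.
#' @export
compute_data_quality <- function(rec, poster = default_poster(),
                                 mode = c("pose_estimated", "fixed_distance"),
                                 assumed_distance = poster$assumed_distance,
                                 params = classifier_params(),
                                 min_match_dur_ms = 50,
                                 geometry_gap_ms = 100) {
  mode <- match.arg(mode)
  eps <- rec$episodes
  if (nrow(eps) == 0) {
    eps <- data.frame(start_ms = min(rec$gaze$timestamp_ms),
                      end_ms = max(rec$gaze$timestamp_ms) + 1,
                      label = "full-recording")
  }
  out <- vector("list", nrow(eps))
  for (e in seq_len(nrow(eps))) {
    sl <- slice_episode(rec, eps$start_ms[e], eps$end_ms[e])
    out[[e]] <- episode_data_quality(
      sl, poster, mode, assumed_distance, params, min_match_dur_ms,
      geometry_gap_ms, label = eps$label[e]
    )
  }
  structure(out, class = "episode_dq_list")
}

episode_data_quality <- function(sl, poster, mode, assumed_distance, params,
                                 min_match_dur_ms, geometry_gap_ms, label) {
  tp <- target_positions(poster)
  targets <- data.frame(
    target_id = tp[, "id"], accuracy_deg = NA_real_, rms_s2s_deg = NA_real_,
    std_deg = NA_real_, n_samples = 0L, viewing_distance_mm = NA_real_,
    eye_x_mm = NA_real_, eye_y_mm = NA_real_, eye_z_mm = NA_real_,
    distance_mm = NA_real_
  )
  empty <- list(episode = list(label = label), targets = targets,
                data_loss_percent = NA_real_,
                gaze_range_deg = c(horizontal = NA_real_, vertical = NA_real_),
                mode = mode, series = NULL, fixations = NULL, matches = NULL)
  if (nrow(sl$gaze) == 0) return(structure(empty, class = "episode_dq"))

  geoms <- fill_missing_geometry(frame_geometries(sl, poster), geometry_gap_ms)
  series <- map_gaze(sl, geoms, poster, mode, assumed_distance)
  fx <- classify_fixations(series, params)
  matches <- match_targets(fx, poster, min_match_dur_ms)
  si <- interpolate_gaps(series, params$max_interp_gap_ms)

  for (i in seq_len(nrow(matches))) {
    fi <- matches$fixation_row[i]
    if (is.na(fi)) next
    idx <- fx$start_idx[fi]:fx$end_idx[fi]
    vidx <- idx[series$valid[idx]]
    if (!length(vidx)) next
    eye <- c(stats::median(series$eye_x_mm[vidx]),
             stats::median(series$eye_y_mm[vidx]),
             stats::median(series$eye_z_mm[vidx]))
    t_xy <- c(tp[i, "x"], tp[i, "y"])
    ctr <- c(fx$centroid_x_mm[fi], fx$centroid_y_mm[fi])
    prec <- precision_deg(si, fx$start_idx[fi], fx$end_idx[fi], t_xy)
    targets$accuracy_deg[i] <- accuracy_deg(ctr, t_xy, eye)
    targets$rms_s2s_deg[i] <- prec[["rms_s2s_deg"]]
    targets$std_deg[i] <- prec[["std_deg"]]
    targets$n_samples[i] <- as.integer(prec[["n"]])
    targets$viewing_distance_mm[i] <- sqrt(sum((c(t_xy, 0) - eye)^2))
    targets$eye_x_mm[i] <- eye[1]; targets$eye_y_mm[i] <- eye[2]
    targets$eye_z_mm[i] <- eye[3]
    targets$distance_mm[i] <- matches$distance_mm[i]
  }
  gr <- gaze_range(matches, fx, series, sl$calibration)
  structure(
    list(episode = list(label = label,
                        start_ms = sl$episodes$start_ms[1],
                        end_ms = sl$episodes$end_ms[1]),
         targets = targets,
         data_loss_percent = data_loss(sl),
         gaze_range_deg = gr, mode = mode,
         series = series, fixations = fx, matches = matches),
    class = "episode_dq"
  )
}

#' @export
print.episode_dq <- function(x, ...) {
  m <- sum(!is.na(x$targets$accuracy_deg))
  cat(sprintf("<episode_dq> '%s' (%s): %d/%d targets matched, mean accuracy %.2f deg, data loss %.1f%%\n",
              x$episode$label, x$mode, m, nrow(x$targets),
              mean(x$targets$accuracy_deg, na.rm = TRUE), x$data_loss_percent))
  invisible(x)
}

#' Summarize data-quality results across recordings and episodes
#'
#' One row per recording x episode x target, or — with
#' `average_over_targets` — one row per recording x episode holding the mean
#' over matched targets (unmatched targets are excluded from averages and
#' counted in `n_unmatched`).
#'
#' @param results Named list: recording name -> `episode_dq_list`
#'   ([compute_data_quality()] output), or a single `episode_dq_list`.
#' @param average_over_targets Collapse targets to their mean (default
#'   FALSE).
#' @return data.frame with columns `recording`, `episode`, `target_id` (or
#'   `"mean"`), `accuracy_deg`, `rms_s2s_deg`, `std_deg`,
#'   `data_loss_percent`, `gaze_range_h_deg`, `gaze_range_v_deg`,
#'   `viewing_distance_mm`, `mode`, `n_samples`, `n_unmatched`.
#' @export
summarize_data_quality <- function(results, average_over_targets = FALSE) {
  if (inherits(results, "episode_dq_list")) results <- list(recording = results)
  rows <- list()
  for (rn in names(results)) {
    for (dq in results[[rn]]) {
      tg <- dq$targets
      n_unmatched <- sum(is.na(tg$accuracy_deg))
      if (average_over_targets) {
        rows[[length(rows) + 1L]] <- data.frame(
          recording = rn, episode = dq$episode$label, target_id = "mean",
          accuracy_deg = mean(tg$accuracy_deg, na.rm = TRUE),
          rms_s2s_deg = mean(tg$rms_s2s_deg, na.rm = TRUE),
          std_deg = mean(tg$std_deg, na.rm = TRUE),
          data_loss_percent = dq$data_loss_percent,
          gaze_range_h_deg = dq$gaze_range_deg[["horizontal"]],
          gaze_range_v_deg = dq$gaze_range_deg[["vertical"]],
          viewing_distance_mm = mean(tg$viewing_distance_mm, na.rm = TRUE),
          mode = dq$mode, n_samples = sum(tg$n_samples),
          n_unmatched = n_unmatched
        )
      } else {
        for (i in seq_len(nrow(tg))) {
          rows[[length(rows) + 1L]] <- data.frame(
            recording = rn, episode = dq$episode$label,
            target_id = as.character(tg$target_id[i]),
            accuracy_deg = tg$accuracy_deg[i],
            rms_s2s_deg = tg$rms_s2s_deg[i], std_deg = tg$std_deg[i],
            data_loss_percent = dq$data_loss_percent,
            gaze_range_h_deg = dq$gaze_range_deg[["horizontal"]],
            gaze_range_v_deg = dq$gaze_range_deg[["vertical"]],
            viewing_distance_mm = tg$viewing_distance_mm[i],
            mode = dq$mode, n_samples = tg$n_samples[i],
            n_unmatched = n_unmatched
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
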