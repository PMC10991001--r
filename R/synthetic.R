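# look-at rotation: camera z axis toward `at`, image x/y co-oriented with
# the poster's x (right) / y (down). Rows of the returned matrix are the
# camera axes in poster coordinates: p_cam = R %*% (p - eye).
look_at_rotation <- function(eye, at = c(0, 0, 0)) {
  f <- at - eye
  f <- f / sqrt(sum(f^2))
  down <- c(0, 1, 0)
  x <- c(down[2] * f[3] - down[3] * f[2],
         down[3] * f[1] - down[1] * f[3],
         down[1] * f[2] - down[2] * f[1])
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop("degenerate look-at direction", call. = FALSE)
  x <- x / nx
  y <- c(f[2] * x[3] - f[3] * x[2],
         f[3] * x[1] - f[1] * x[3],
         f[1] * x[2] - f[2] * x[1])
  rbind(x, y, f, deparse.level = 0)
}

#' Eye/head trajectories for the simulator
#'
#' `trajectory_static` keeps the eye (and the scene camera, co-located with
#' it) at one position, aimed at the poster centre. `trajectory_sway`
#' oscillates the position sinusoidally along z (and optionally x) around a
#' base position — a participant slowly rocking toward and away from the
#' poster — re-aiming at the poster centre every sample. Zero amplitude
#' reduces sway to static.
#'
#' @param pos,base Eye position, mm in the poster frame (z < 0).
#' @param amplitude_z,amplitude_x Sway amplitudes, mm (>= 0).
#' @param period_ms Sway period, ms.
#' @return A function `t_ms -> list(position, rotation)` with `rotation` the
#'   poster-to-camera matrix.
#' @export
trajectory_static <- function(pos = c(0, 0, -600)) {
  stopifnot(length(pos) == 3)
  R <- look_at_rotation(pos)
  force(pos)
  function(t_ms) list(position = pos, rotation = R)
}

#' @rdname trajectory_static
#' @export
trajectory_sway <- function(amplitude_z = 100, period_ms = 2000,
                            base = c(0, 0, -600), amplitude_x = 0) {
  stopifnot(amplitude_z >= 0, amplitude_x >= 0, period_ms > 0)
  function(t_ms) {
    ph <- 2 * pi * t_ms / period_ms
    pos <- base + c(amplitude_x * sin(ph), 0, amplitude_z * sin(ph))
    list(position = pos, rotation = look_at_rotation(pos))
  }
}

#' Simulation configuration
#'
#' Defines one synthetic validation recording. The defaults emulate the
#' standard operator instruction: the participant fixates the nine targets
#' in reading order for one second each from the assumed viewing position,
#' head still. Inaccuracy is injected as a constant Fick-angle offset of the
#' gaze direction, imprecision as white Gaussian angular noise, data loss as
#' per-sample Bernoulli dropout, and marker-detection noise as Gaussian
#' pixel jitter on the projected corner positions.
#'
#' @param poster A `poster_spec`.
#' @param calib A `camera_calibration` for the simulated scene camera.
#' @param eye_trajectory A trajectory function ([trajectory_static()]).
#' @param dwell_ms Dwell per target, ms (default 1000).
#' @param order Target visiting order (ids; default all targets in reading
#'   order).
#' @param offset_deg Constant gaze offset `c(azimuth, elevation)`, degrees.
#' @param noise_sigma_deg SD of white angular noise per Fick component,
#'   degrees.
#' @param loss_prob Per-sample probability of a missing gaze sample.
#' @param corner_noise_px SD of marker-corner jitter, px.
#' @param rate_hz Gaze and video sampling rate (default 50).
#' @param seed RNG seed; the same seed reproduces the recording bit for bit.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(poster = default_poster(),
                              calib = camera_calibration(1000, 1000, 960, 540),
                              eye_trajectory = trajectory_static(
                                c(0, 0, -poster$assumed_distance)),
                              dwell_ms = 1000,
                              order = vapply(poster$targets, `[[`, integer(1), "id"),
                              offset_deg = c(0, 0),
                              noise_sigma_deg = 0,
                              loss_prob = 0,
                              corner_noise_px = 0,
                              rate_hz = 50,
                              seed = NULL) {
  stopifnot(rate_hz > 0, dwell_ms > 0, loss_prob >= 0, loss_prob <= 1,
            noise_sigma_deg >= 0, corner_noise_px >= 0,
            length(offset_deg) == 2)
  structure(
    list(poster = poster, calib = calib, eye_trajectory = eye_trajectory,
         dwell_ms = dwell_ms, order = order, offset_deg = offset_deg,
         noise_sigma_deg = noise_sigma_deg, loss_prob = loss_prob,
         corner_noise_px = corner_noise_px, rate_hz = rate_hz, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate a validation recording with known ground truth
#'
#' Generates gaze samples and per-frame marker-corner observations for the
#' scanpath defined by the configuration. Per sample: the true gaze
#' direction runs from the eye to the current target; the reported direction
#' perturbs its Fick angles by the constant offset plus Gaussian noise; the
#' reported poster position is the intersection of the reported ray with the
#' poster plane; the gaze pixel is the scene-camera projection (with
#' distortion) of that position; marker corners are the projections of the
#' marker geometry plus pixel jitter. A single validation-episode annotation
#' spans the scanpath. Deterministic under a fixed seed.
#'
#' @param cfg A `simulation_config`.
#' @return A list with `recording` (a `recording`) and `ground_truth` (a
#'   data.frame aligned 1:1 with the gaze samples: timestamp, target id,
#'   true eye position, true/reported gaze, missing flag).
#' @export
simulate_recording <- function(cfg) {
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(cfg$seed)
  }
  tp <- target_positions(cfg$poster)
  dt <- 1000 / cfg$rate_hz
  n_per <- max(1L, round(cfg$dwell_ms / dt))
  n <- n_per * length(cfg$order)
  ts <- (seq_len(n) - 1L) * dt
  tgt_ids <- rep(cfg$order, each = n_per)
  corner_mm <- lapply(cfg$poster$markers, function(m) cbind(marker_corners_mm(m), 0))
  mk_ids <- vapply(cfg$poster$markers, `[[`, integer(1), "id")

  gaze <- data.frame(timestamp_ms = ts, frame_idx = seq_len(n) - 1L,
                     gaze_x_px = NA_real_, gaze_y_px = NA_real_)
  gt <- data.frame(timestamp_ms = ts, target_id = tgt_ids,
                   eye_x_mm = NA_real_, eye_y_mm = NA_real_, eye_z_mm = NA_real_,
                   true_az_deg = NA_real_, true_el_deg = NA_real_,
                   poster_x_mm = NA_real_, poster_y_mm = NA_real_,
                   missing = FALSE)
  mk_rows <- vector("list", n)
  az_noise <- stats::rnorm(n, 0, cfg$noise_sigma_deg)
  el_noise <- stats::rnorm(n, 0, cfg$noise_sigma_deg)
  lost <- stats::runif(n) < cfg$loss_prob

  for (i in seq_len(n)) {
    pose <- cfg$eye_trajectory(ts[i])
    E <- pose$position; R <- pose$rotation
    if (E[3] >= 0) stop("eye trajectory crosses the poster plane", call. = FALSE)
    ti <- match(tgt_ids[i], tp[, "id"])
    T3 <- c(tp[ti, "x"], tp[ti, "y"], 0)
    d <- T3 - E
    fick <- direction_to_fick(d)
    gt$true_az_deg[i] <- fick[1]; gt$true_el_deg[i] <- fick[2]
    gt$eye_x_mm[i] <- E[1]; gt$eye_y_mm[i] <- E[2]; gt$eye_z_mm[i] <- E[3]
    drep <- fick_to_direction(fick[1] + cfg$offset_deg[1] + az_noise[i],
                              fick[2] + cfg$offset_deg[2] + el_noise[i])[1, ]
    if (drep[3] <= 0) stop("reported gaze ray does not hit the poster plane",
                           call. = FALSE)
    P <- E + (-E[3] / drep[3]) * drep
    gt$poster_x_mm[i] <- P[1]; gt$poster_y_mm[i] <- P[2]
    if (!lost[i]) {
      p_cam <- as.numeric(R %*% (P - E))
      px <- project_points(p_cam, cfg$calib)
      gaze$gaze_x_px[i] <- px[1, 1]; gaze$gaze_y_px[i] <- px[1, 2]
    } else {
      gt$missing[i] <- TRUE
    }
    crn <- lapply(seq_along(corner_mm), function(m) {
      pc <- t(R %*% (t(corner_mm[[m]]) - E))
      if (any(pc[, 3] <= 0)) return(NULL)
      px <- project_points(pc, cfg$calib)
      if (cfg$corner_noise_px > 0) {
        px <- px + matrix(stats::rnorm(8, 0, cfg$corner_noise_px), 4, 2)
      }
      data.frame(frame_idx = i - 1L, marker_id = mk_ids[m],
                 x1 = px[1, 1], y1 = px[1, 2], x2 = px[2, 1], y2 = px[2, 2],
                 x3 = px[3, 1], y3 = px[3, 2], x4 = px[4, 1], y4 = px[4, 2])
    })
    mk_rows[[i]] <- do.call(rbind, crn[!vapply(crn, is.null, logical(1))])
  }
  markers <- do.call(rbind, mk_rows)
  episodes <- data.frame(start_ms = 0, end_ms = n * dt, label = "validation")
  rec <- recording(gaze, markers, episodes, calibration = cfg$calib,
                   meta = list(source = "synthetic"))
  list(recording = rec, ground_truth = gt)
}

#' Write a simulated recording plus its ground truth to disk
#'
#' Writes the interchange layout of [write_recording()] and a
#' `ground_truth.csv` alongside it.
#'
#' @param sim Output of [simulate_recording()].
#' @param dir_path Directory path.
#' @return `dir_path`, invisibly.
#' @export
write_simulation <- function(sim, dir_path) {
  write_recording(sim$recording, dir_path)
  utils::write.csv(sim$ground_truth, file.path(dir_path, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir_path)
}
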