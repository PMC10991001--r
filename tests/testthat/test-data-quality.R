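fix_row <- function(start, dur, x, y) {
  data.frame(start_ms = start, end_ms = start + dur, duration_ms = dur,
             centroid_x_mm = x, centroid_y_mm = y,
             start_idx = 1L, end_idx = 2L, n_valid = 2L)
}

test_that("target matching is nearest-first, injective, duration-gated", {
  p <- default_poster()
  tp <- cbind(vapply(p$targets, `[[`, numeric(1), "x"),
              vapply(p$targets, `[[`, numeric(1), "y"))
  # nine fixations each within 5 mm of a distinct target: perfect bijection
  set.seed(5)
  fx <- do.call(rbind, lapply(1:9, function(i) {
    fix_row((i - 1) * 1000, 800, tp[i, 1] + runif(1, -5, 5),
            tp[i, 2] + runif(1, -5, 5))
  }))
  m <- match_targets(fx, p)
  expect_equal(m$fixation_row, 1:9)
  expect_true(all(m$distance_mm < sqrt(50)))

  # a 40 ms fixation is never matched
  m40 <- match_targets(fix_row(0, 40, 0, 0), p)
  expect_true(all(is.na(m40$fixation_row)))
  # at exactly 50 ms it becomes eligible
  m50 <- match_targets(fix_row(0, 50, 0, 0), p)
  expect_equal(sum(!is.na(m50$fixation_row)), 1L)

  # one fixation between two targets goes to the nearer one only
  two <- poster_spec(list(target_spec(1, 0, 0), target_spec(2, 40, 0)),
                     list(marker_spec(0, 0, 200, 41.9)))
  m2 <- match_targets(fix_row(0, 500, 10, 0), two)
  expect_equal(m2$fixation_row, c(1L, NA))
  expect_equal(m2$distance_mm[1], 10)

  # injective and total over min(#targets, #eligible) on random inputs
  for (rep in 1:5) {
    fxr <- do.call(rbind, lapply(1:6, function(i) {
      fix_row((i - 1) * 500, sample(c(30, 100, 400), 1),
              runif(1, -120, 120), runif(1, -100, 100))
    }))
    mr <- match_targets(fxr, p)
    matched <- mr$fixation_row[!is.na(mr$fixation_row)]
    expect_equal(anyDuplicated(matched), 0L)
    expect_equal(length(matched), min(9L, sum(fxr$duration_ms >= 50)))
  }
})

test_that("accuracy is the eye-referred angle between gaze and target", {
  # atan oracle at two viewing distances
  expect_equal(accuracy_deg(c(10.47, 0), c(0, 0), c(0, 0, -600)),
               atan(10.47 / 600) * 180 / pi)
  expect_equal(round(accuracy_deg(c(10.47, 0), c(0, 0), c(0, 0, -600)), 3), 1.000)
  expect_equal(round(accuracy_deg(c(10.47, 0), c(0, 0), c(0, 0, -300)), 3), 1.999)
  expect_lt(accuracy_deg(c(25, -14), c(25, -14), c(0, 0, -600)), 1e-6)
})

test_that("precision formulas agree with closed forms", {
  # identical samples: both zero
  s <- make_series(rep(5, 10), rep(5, 10))
  pr <- precision_deg(s, 1, 10, c(5, 5))
  expect_equal(unname(pr[1:2]), c(0, 0))

  # alternating +/-0.1 deg azimuth: RMS-S2S 0.2, STD 0.1 exactly
  n <- 50
  az <- rep(c(0.1, -0.1), n / 2)
  x <- 600 * tan(az * pi / 180)
  s2 <- make_series(x, rep(0, n))
  pr2 <- precision_deg(s2, 1, n, c(0, 0))
  expect_equal(unname(pr2[["rms_s2s_deg"]]), 0.2, tolerance = 1e-9)
  expect_equal(unname(pr2[["std_deg"]]), 0.1, tolerance = 1e-9)

  # white Gaussian az/el noise sigma = 0.1 deg, n = 500:
  # E[RMS] = 2 sigma, E[STD] = sigma sqrt(2), each within 10%
  set.seed(99)
  az <- rnorm(500, 0, 0.1); el <- rnorm(500, 0, 0.1)
  x <- 600 * tan(az * pi / 180)
  y <- -sqrt(x^2 + 600^2) * tan(el * pi / 180)
  s3 <- make_series(x, y)
  pr3 <- precision_deg(s3, 1, 500, c(0, 0))
  expect_equal(unname(pr3[["rms_s2s_deg"]]), 0.2, tolerance = 0.1)
  expect_equal(unname(pr3[["std_deg"]]), 0.1 * sqrt(2), tolerance = 0.1)
  # white noise: RMS/STD ratio near sqrt(2)
  expect_equal(unname(pr3[["rms_s2s_deg"]] / pr3[["std_deg"]]), sqrt(2),
               tolerance = 0.1)

  # drift: slow ramp, small successive steps -> ratio below sqrt(2)
  ramp <- seq(0, 0.5, length.out = 500)
  s4 <- make_series(600 * tan(ramp * pi / 180), rep(0, 500))
  pr4 <- precision_deg(s4, 1, 500, c(0, 0))
  expect_lt(pr4[["rms_s2s_deg"]] / pr4[["std_deg"]], sqrt(2))
  # anti-correlated jitter: alternation -> ratio above sqrt(2)
  expect_gt(pr2[["rms_s2s_deg"]] / pr2[["std_deg"]], sqrt(2))

  # one valid sample: precision missing
  pr1 <- precision_deg(make_series(0, 0), 1, 1, c(0, 0))
  expect_true(is.na(pr1[["rms_s2s_deg"]]))
})

test_that("gaze range needs two matches and vanishes under head pointing", {
  sim <- simulate_recording(simulation_config(dwell_ms = 400, seed = 31))
  dq <- compute_data_quality(sim$recording, mode = "pose_estimated")[[1]]
  expect_equal(unname(dq$gaze_range_deg), c(20, 17.5), tolerance = 1e-6)

  # a single matched target yields no range
  gr1 <- gaze_range(dq$matches[5, , drop = FALSE], dq$fixations, dq$series,
                    sim$recording$calibration)
  expect_true(all(is.na(gr1)))

  # head rotated to aim at each target (eye-in-head constant): range ~ 0
  p <- default_poster()
  tp <- cbind(vapply(p$targets, `[[`, numeric(1), "x"),
              vapply(p$targets, `[[`, numeric(1), "y"))
  head_track <- function(t_ms) {
    i <- min(nrow(tp), floor(t_ms / 400) + 1)
    pos <- c(0, 0, -600)
    list(position = pos,
         rotation = gazeval:::look_at_rotation(pos, c(tp[i, 1], tp[i, 2], 0)))
  }
  sim2 <- simulate_recording(simulation_config(
    dwell_ms = 400, eye_trajectory = head_track, seed = 32))
  dq2 <- compute_data_quality(sim2$recording, mode = "pose_estimated")[[1]]
  expect_lt(max(abs(dq2$gaze_range_deg)), 0.05)
  # while the accuracy is unaffected by how the head moved
  expect_lt(max(dq2$targets$accuracy_deg), 0.01)
})

test_that("fixed-distance error ratio follows the two-distance trigonometry", {
  expect_ratio <- function(phys, assumed, offset) {
    sim <- simulate_recording(simulation_config(
      eye_trajectory = trajectory_static(c(0, 0, -phys)),
      offset_deg = c(offset, 0), dwell_ms = 400, seed = 77))
    dq_pose <- compute_data_quality(sim$recording, mode = "pose_estimated")[[1]]
    dq_fix <- compute_data_quality(sim$recording, mode = "fixed_distance",
                                   assumed_distance = assumed)[[1]]
    ratio <- fixed_distance_error_ratio(dq_fix$targets, dq_pose$targets)
    # central target: gaze lands r mm from it; predicted ratio from r
    r <- dq_pose$targets$distance_mm[5]
    predicted <- 100 * atan(r / assumed) / atan(r / phys)
    expect_equal(ratio$accuracy_ratio_percent[5], predicted, tolerance = 0.02)
    ratio$accuracy_ratio_percent[5]
  }
  r_800 <- expect_ratio(800, 600, 1)
  expect_equal(r_800, 133.3, tolerance = 0.02)
  # matching distances: the assumption is harmless
  r_600 <- expect_ratio(600, 600, 1)
  expect_equal(r_600, 100, tolerance = 1e-6)
})

test_that("summaries average only over matched targets", {
  sim <- simulate_recording(simulation_config(dwell_ms = 400, seed = 41,
                                              offset_deg = c(0.5, 0.5)))
  dq <- compute_data_quality(sim$recording, mode = "pose_estimated")
  rows <- summarize_data_quality(list(recA = dq))
  expect_equal(nrow(rows), 9L)
  expect_true(all(rows$recording == "recA"))
  avg <- summarize_data_quality(list(recA = dq), average_over_targets = TRUE)
  expect_equal(nrow(avg), 1L)
  expect_equal(avg$accuracy_deg, mean(rows$accuracy_deg))

  # synthetic check of the mean with hand-set accuracies
  dq2 <- dq
  dq2[[1]]$targets$accuracy_deg <- seq(0.5, 1.3, by = 0.1)
  avg2 <- summarize_data_quality(list(r = dq2), average_over_targets = TRUE)
  expect_equal(avg2$accuracy_deg, 0.9)
  # one unmatched target: mean over the remaining eight
  dq3 <- dq
  dq3[[1]]$targets$accuracy_deg <- c(NA, seq(0.6, 1.3, by = 0.1))
  avg3 <- summarize_data_quality(list(r = dq3), average_over_targets = TRUE)
  expect_equal(avg3$accuracy_deg, mean(seq(0.6, 1.3, by = 0.1)))
})
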