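test_that("gap interpolation bridges short gaps only and flags its output", {
  s <- make_series(c(0, NA, 2), c(0, NA, 2), valid = c(TRUE, FALSE, TRUE))
  out <- interpolate_gaps(s, 100)
  expect_equal(out$poster_x_mm[2], 1)  # midpoint
  expect_equal(out$poster_y_mm[2], 1)
  expect_true(out$interpolated[2])
  expect_true(out$valid[2])

  # 300 ms gap at 50 Hz with a 100 ms cap: untouched
  valid <- rep(TRUE, 40); valid[11:25] <- FALSE
  s2 <- make_series(rep(0, 40), rep(0, 40), valid = valid)
  out2 <- interpolate_gaps(s2, 100)
  expect_true(all(is.na(out2$poster_x_mm[11:25])))
  expect_false(any(out2$interpolated))

  # no gaps: identity apart from the flag column
  s3 <- make_series(1:10, 1:10)
  out3 <- interpolate_gaps(s3, 100)
  expect_equal(out3$poster_x_mm, s3$poster_x_mm)
  expect_false(any(out3$interpolated))
})

test_that("clustering weights are zero for stationary gaze and peak at jumps", {
  # constant position: no transitions anywhere
  s <- make_series(rep(10, 60), rep(-5, 60))
  w <- clustering_weights(s)
  expect_true(all(w == 0))

  # one instantaneous 5 deg jump (52.6 mm at 600 mm): the two samples at the
  # jump carry the maximum weight, every covering window transitions there
  jump_mm <- 600 * tan(5 * pi / 180)
  x <- c(rep(0, 40), rep(jump_mm, 40))
  set.seed(8)
  s2 <- make_series(x + rnorm(80, 0, 0.15), rnorm(80, 0, 0.15))
  w2 <- clustering_weights(s2)
  expect_equal(sort(order(w2, decreasing = TRUE)[1:2]), c(40, 41))
  expect_gte(min(w2[40:41]), 0.9)
  expect_lt(mean(w2[c(1:30, 51:80)]), 0.2)
})

test_that("two-cluster windows produce exactly one transition pair", {
  # 6-sample toy window, enumeration oracle: labels 1 1 1 2 2 2 -> one
  # transition, samples 3 and 4 flanking it
  xy <- cbind(c(0, 0.1, -0.1, 50, 50.1, 49.9), c(0, 0, 0.1, 50, 50, 49.9))
  lab <- gazeval:::two_means_labels(xy)
  expect_equal(lab, c(1L, 1L, 1L, 2L, 2L, 2L))
  # identical points: degenerate, single label
  expect_equal(gazeval:::two_means_labels(matrix(1, 6, 2)), rep(1L, 6))
})

test_that("stationary series yields a single full-span fixation", {
  set.seed(9)
  s <- make_series(rnorm(50, 0, 0.1), rnorm(50, 0, 0.1))  # 1 s at 50 Hz
  fx <- classify_fixations(s)
  expect_equal(nrow(fx), 1L)
  expect_lte(fx$start_ms, 40)
  expect_gte(fx$end_ms, 940)
  expect_equal(fx$centroid_x_mm, mean(s$poster_x_mm[fx$start_idx:fx$end_idx]))
})

test_that("noiseless nine-dwell scanpath recovers all nine fixations exactly", {
  p <- default_poster()
  tp <- cbind(vapply(p$targets, `[[`, numeric(1), "x"),
              vapply(p$targets, `[[`, numeric(1), "y"))
  s <- make_scanpath_series(tp, dwell_n = 40, sigma_deg = 0)  # 800 ms dwells
  fx <- classify_fixations(s)
  expect_equal(nrow(fx), 9L)
  expect_lt(max(abs(fx$centroid_x_mm - tp[, 1])), 0.1)
  expect_lt(max(abs(fx$centroid_y_mm - tp[, 2])), 0.1)
})

test_that("dwell recovery holds under noise with onsets within 40 ms", {
  p <- default_poster()
  tp <- cbind(vapply(p$targets, `[[`, numeric(1), "x"),
              vapply(p$targets, `[[`, numeric(1), "y"))
  for (seed in 1:5) {
    s <- make_scanpath_series(tp, dwell_n = 50, sigma_deg = 0.25, seed = seed)
    fx <- classify_fixations(s)
    expect_equal(nrow(fx), 9L)
    true_onsets <- (0:8) * 1000
    true_offsets <- (0:8) * 1000 + 980
    expect_lt(max(abs(fx$start_ms - true_onsets)), 41)
    expect_lt(max(abs(fx$end_ms - true_offsets)), 41)
  }
})

test_that("segmentation is translation invariant", {
  p <- default_poster()
  tp <- cbind(vapply(p$targets, `[[`, numeric(1), "x"),
              vapply(p$targets, `[[`, numeric(1), "y"))
  s <- make_scanpath_series(tp, dwell_n = 30, sigma_deg = 0.2, seed = 12)
  s2 <- s
  s2$poster_x_mm <- s2$poster_x_mm + 500
  s2$poster_y_mm <- s2$poster_y_mm - 120
  f1 <- classify_fixations(s)
  f2 <- classify_fixations(s2)
  expect_equal(f2$start_ms, f1$start_ms)
  expect_equal(f2$end_ms, f1$end_ms)
  expect_equal(f2$centroid_x_mm, f1$centroid_x_mm + 500)
})

test_that("lowering lambda never increases total fixation duration", {
  p <- default_poster()
  tp <- cbind(vapply(p$targets, `[[`, numeric(1), "x"),
              vapply(p$targets, `[[`, numeric(1), "y"))
  s <- make_scanpath_series(tp, dwell_n = 40, sigma_deg = 0.3, seed = 21)
  total <- vapply(c(3, 2, 1, 0.5, 0.25), function(lam) {
    fx <- classify_fixations(s, classifier_params(weight_cutoff_lambda = lam))
    sum(fx$duration_ms)
  }, numeric(1))
  expect_true(all(diff(total) <= 1e-9))
})

test_that("degenerate series give empty fixation lists", {
  empty <- make_series(numeric(0), numeric(0))
  expect_equal(nrow(classify_fixations(empty)), 0L)
  all_missing <- make_series(rep(NA_real_, 30), rep(NA_real_, 30),
                             valid = rep(FALSE, 30))
  expect_equal(nrow(classify_fixations(all_missing)), 0L)
})
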