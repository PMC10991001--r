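#' Fixation classifier parameters
#'
#' Tuning knobs of the two-means clustering fixation classifier. Defaults
#' follow the classifier family this implementation belongs to (I2MC-style
#' windowed two-means weighting), at values appropriate for wearable
#' trackers sampling at 50-120 Hz.
#'
#' @param window_ms Sliding-window length, ms (default 200).
#' @param max_interp_gap_ms Longest run of missing samples bridged by linear
#'   interpolation before clustering, ms (default 100).
#' @param weight_cutoff_lambda Cutoff multiplier: fixation samples are those
#'   with clustering weight below mean + lambda * SD (default 2).
#' @param merge_max_gap_ms Merge candidate fixations separated by at most
#'   this gap, ms (default 30).
#' @param merge_max_dist_deg ... and by at most this angular centroid
#'   distance, degrees as seen from the eye (default 0.7).
#' @param min_fix_dur_ms Discard fixations shorter than this, ms (default 40).
#' @return A named list of class `classifier_params`.
#' @export
classifier_params <- function(window_ms = 200, max_interp_gap_ms = 100,
                              weight_cutoff_lambda = 2, merge_max_gap_ms = 30,
                              merge_max_dist_deg = 0.7, min_fix_dur_ms = 40) {
  p <- list(window_ms = window_ms, max_interp_gap_ms = max_interp_gap_ms,
            weight_cutoff_lambda = weight_cutoff_lambda,
            merge_max_gap_ms = merge_max_gap_ms,
            merge_max_dist_deg = merge_max_dist_deg,
            min_fix_dur_ms = min_fix_dur_ms)
  if (any(unlist(p) <= 0)) stop("classifier parameters must be positive", call. = FALSE)
  structure(p, class = "classifier_params")
}

#' Interpolate short gaps in a mapped gaze series
#'
#' Linearly interpolates poster positions (and eye positions) across runs of
#' invalid samples no longer than `max_gap_ms`; interpolated samples are
#' flagged in a new `interpolated` column and participate in clustering but
#' not in fixation centroids. Longer gaps are left untouched.
#'
#' @param series A `poster_gaze_series`.
#' @param max_gap_ms Longest bridgeable gap, ms (default 100).
#' @return The series with gaps filled and an `interpolated` flag column.
#' @export
interpolate_gaps <- function(series, max_gap_ms = 100) {
  s <- series
  s$interpolated <- FALSE
  n <- nrow(s)
  if (n == 0 || all(s$valid) || !any(s$valid)) return(s)
  valid_idx <- which(s$valid)
  runs <- rle(!s$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    if (a == 1L || b == n) next  # no anchor on one side
    gap <- s$timestamp_ms[b + 1L] - s$timestamp_ms[a - 1L]
    if (gap > max_gap_ms) next
    t0 <- s$timestamp_ms[a - 1L]; t1 <- s$timestamp_ms[b + 1L]
    w <- (s$timestamp_ms[a:b] - t0) / (t1 - t0)
    for (col in c("poster_x_mm", "poster_y_mm", "eye_x_mm", "eye_y_mm", "eye_z_mm")) {
      s[[col]][a:b] <- (1 - w) * s[[col]][a - 1L] + w * s[[col]][b + 1L]
    }
    s$interpolated[a:b] <- TRUE
    s$valid[a:b] <- TRUE
    s$reason[a:b] <- "interpolated"
  }
  s
}

# two-means clustering of a window, initialized by splitting the window at
# its temporal midpoint; plain Lloyd iterations. Returns integer labels.
# Degenerate windows (all points identical, or a cluster emptying) yield a
# single label, i.e. no transition.
two_means_labels <- function(xy, max_iter = 100) {
  n <- nrow(xy)
  half <- floor(n / 2)
  c1 <- colMeans(xy[1:half, , drop = FALSE])
  c2 <- colMeans(xy[(half + 1):n, , drop = FALSE])
  if (all(abs(c1 - c2) < 1e-12)) return(rep(1L, n))
  lab <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d1 <- (xy[, 1] - c1[1])^2 + (xy[, 2] - c1[2])^2
    d2 <- (xy[, 1] - c2[1])^2 + (xy[, 2] - c2[2])^2
    new_lab <- ifelse(d2 < d1, 2L, 1L)
    if (all(new_lab == lab) && it > 1) break
    lab <- new_lab
    if (!any(lab == 1L) || !any(lab == 2L)) return(rep(1L, n))
    c1 <- colMeans(xy[lab == 1L, , drop = FALSE])
    c2 <- colMeans(xy[lab == 2L, , drop = FALSE])
  }
  lab
}

#' Per-sample clustering weights
#'
#' For every sliding window of length `window_ms` (step one sample) that
#' contains only usable positions and at least four samples, the 2-D poster
#' positions are clustered into two groups by Lloyd's algorithm initialized
#' at the window's temporal midpoint split. The samples flanking each
#' cluster-label transition receive 1/(number of transitions in that
#' window); a sample's weight is its accumulated count divided by the number
#' of processed windows covering it. A saccade sample sits at the single
#' clean transition of every covering window and approaches weight 1; inside
#' a fixation the label flips are many and scattered, so each sample's share
#' stays small.
#'
#' @param series An interpolated `poster_gaze_series`
#'   (see [interpolate_gaps()]).
#' @param params A `classifier_params`.
#' @return Numeric vector of weights, `NA` for samples never covered by a
#'   processed window.
#' @export
clustering_weights <- function(series, params = classifier_params()) {
  n <- nrow(series)
  counts <- numeric(n)
  cover <- numeric(n)
  if (n == 0) return(numeric(0))
  dt <- if (n > 1) stats::median(diff(series$timestamp_ms)) else Inf
  w_smp <- max(2L, round(params$window_ms / dt))
  usable <- series$valid & !is.na(series$poster_x_mm)
  xy_all <- cbind(series$poster_x_mm, series$poster_y_mm)
  if (n >= w_smp && w_smp >= 4L) {
    for (s in seq_len(n - w_smp + 1L)) {
      win <- s:(s + w_smp - 1L)
      if (!all(usable[win])) next
      lab <- two_means_labels(xy_all[win, , drop = FALSE])
      cover[win] <- cover[win] + 1
      tr <- which(lab[-length(lab)] != lab[-1])
      if (length(tr)) {
        # each transition is worth 1/(number of transitions in the window):
        # a clean saccade window has exactly one and contributes full
        # weight, while the scattered label flips of a noisy fixation
        # window share theirs out and stay small
        marked <- unique(c(win[tr], win[tr + 1L]))
        counts[marked] <- counts[marked] + 1 / length(tr)
      }
    }
  }
  out <- ifelse(cover > 0, counts / cover, NA_real_)
  out
}

#' Classify fixations in a mapped gaze series
#'
#' Full classification chain: gap interpolation, windowed two-means
#' clustering weights, a 3-point moving average over the weight series,
#' thresholding at mean + lambda * SD of the smoothed weights,
#' merging of candidate fixations separated by short gaps and small angular
#' centroid distances, and a minimum-duration filter. Centroids are the
#' arithmetic mean of the valid (non-interpolated) member positions.
#'
#' @param series A `poster_gaze_series`.
#' @param params A `classifier_params`.
#' @return A data.frame of class `fixations`: `start_ms`, `end_ms`,
#'   `duration_ms`, `centroid_x_mm`, `centroid_y_mm`, `start_idx`,
#'   `end_idx`, `n_valid` (member sample counts refer to row indices of
#'   `series`).
#' @export
classify_fixations <- function(series, params = classifier_params()) {
  empty <- data.frame(start_ms = numeric(), end_ms = numeric(),
                      duration_ms = numeric(), centroid_x_mm = numeric(),
                      centroid_y_mm = numeric(), start_idx = integer(),
                      end_idx = integer(), n_valid = integer())
  class(empty) <- c("fixations", "data.frame")
  if (nrow(series) == 0 || !any(series$valid)) return(empty)
  orig_valid <- series$valid & !is.na(series$poster_x_mm)
  s <- interpolate_gaps(series, params$max_interp_gap_ms)
  w <- clustering_weights(s, params)
  ok <- !is.na(w)
  if (!any(ok)) return(empty)
  # short moving average over the weight series: the single-scale analogue
  # of averaging weights across time scales, damping one-sample noise spikes
  # that would otherwise cut a fixation in two
  n <- length(w)
  if (n >= 3) {
    wm <- w
    mid <- 2:(n - 1)
    tri <- cbind(w[mid - 1L], w[mid], w[mid + 1L])
    sm <- rowMeans(tri, na.rm = TRUE)
    wm[mid][!is.na(w[mid])] <- sm[!is.na(w[mid])]
    w <- wm
  }
  mu <- mean(w[ok]); sg <- stats::sd(w[ok])
  if (is.na(sg)) sg <- 0
  cutoff <- mu + params$weight_cutoff_lambda * sg
  is_fix <- ok & w <= cutoff
  runs <- rle(is_fix)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- data.frame(a = starts[runs$values], b = ends[runs$values])
  if (nrow(cand) == 0) return(empty)

  centroid_of <- function(a, b) {
    m <- orig_valid[a:b]
    if (!any(m)) m <- s$valid[a:b]  # fall back to interpolated members
    c(mean(s$poster_x_mm[a:b][m]), mean(s$poster_y_mm[a:b][m]))
  }
  eye <- c(stats::median(s$eye_x_mm[s$valid]), stats::median(s$eye_y_mm[s$valid]),
           stats::median(s$eye_z_mm[s$valid]))

  # merge candidates across short, small-amplitude gaps; the gap is the
  # duration of the intervening non-fixation material (one excluded sample
  # at 50 Hz = 20 ms)
  dt <- if (nrow(s) > 1) stats::median(diff(s$timestamp_ms)) else 0
  merged <- list()
  cur <- c(cand$a[1], cand$b[1])
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      gap_ms <- s$timestamp_ms[cand$a[i]] - s$timestamp_ms[cur[2]] - dt
      c1 <- centroid_of(cur[1], cur[2]); c2 <- centroid_of(cand$a[i], cand$b[i])
      ang <- angle_between(c(c1, 0) - eye, c(c2, 0) - eye)
      if (gap_ms <= params$merge_max_gap_ms && ang <= params$merge_max_dist_deg) {
        cur[2] <- cand$b[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(cand$a[i], cand$b[i])
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur

  rows <- lapply(merged, function(m) {
    a <- m[1]; b <- m[2]
    start <- s$timestamp_ms[a]; end <- s$timestamp_ms[b]
    if (end - start < params$min_fix_dur_ms) return(NULL)
    ctr <- centroid_of(a, b)
    data.frame(start_ms = start, end_ms = end, duration_ms = end - start,
               centroid_x_mm = ctr[1], centroid_y_mm = ctr[2],
               start_idx = a, end_idx = b, n_valid = sum(orig_valid[a:b]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("fixations", "data.frame")
  out
}

#' Export a fixation list to CSV
#'
#' @param fixations A `fixations` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  keep <- c("start_ms", "end_ms", "duration_ms", "centroid_x_mm", "centroid_y_mm")
  utils::write.csv(as.data.frame(fixations)[, keep], path, row.names = FALSE)
  invisible(path)
}
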