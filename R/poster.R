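#' Fixation target specification
#'
#' A single printed fixation target on the validation poster. Coordinates are
#' millimetres in the poster frame: origin at the centre of the target grid,
#' x rightward, y downward, z into the poster (a viewer stands at negative z).
#'
#' @param id Integer label, unique within a poster.
#' @param x,y Position on the poster plane, mm.
#' @param appearance `"red"` or `"blue"`. By convention the first (top-left)
#'   target is red and marks the start of the viewing order.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(id, x, y, appearance = c("blue", "red")) {
  appearance <- match.arg(appearance)
  stopifnot(is.numeric(id), length(id) == 1L, is.finite(x), is.finite(y))
  structure(
    list(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
         appearance = appearance),
    class = "target_spec"
  )
}

#' Fiducial marker specification
#'
#' A square fiducial (ArUco) marker printed on the poster. `id` is the index
#' into the marker dictionary used by the detector; `size` is the printed side
#' length in mm; `rotation` an in-plane rotation in degrees.
#'
#' @param id Dictionary index (unique within a poster).
#' @param center_x,center_y Marker centre, mm in the poster frame.
#' @param size Side length, mm; must be positive.
#' @param rotation In-plane rotation, degrees (default 0).
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(id, center_x, center_y, size, rotation = 0) {
  stopifnot(is.numeric(id), length(id) == 1L)
  if (!is.numeric(size) || size <= 0) {
    stop("marker ", id, ": size must be > 0", call. = FALSE)
  }
  structure(
    list(id = as.integer(id), center_x = as.numeric(center_x),
         center_y = as.numeric(center_y), size = as.numeric(size),
         rotation = as.numeric(rotation)),
    class = "marker_spec"
  )
}

#' Poster specification
#'
#' The planar validation surface: fixation targets plus fiducial markers, all
#' on the plane z = 0, with the assumed perpendicular viewing distance used
#' when no camera calibration is available.
#'
#' @param targets List of [target_spec()] objects (at least one).
#' @param markers List of [marker_spec()] objects (at least one).
#' @param assumed_distance Assumed perpendicular viewing distance, mm
#'   (default 600).
#' @param paper_size Physical sheet size `c(width, height)` in mm
#'   (default A2 portrait, 420 x 594).
#' @return An object of class `poster_spec`.
#' @export
poster_spec <- function(targets, markers, assumed_distance = 600,
                        paper_size = c(420, 594)) {
  p <- structure(
    list(targets = targets, markers = markers,
         assumed_distance = as.numeric(assumed_distance),
         paper_size = as.numeric(paper_size)),
    class = "poster_spec"
  )
  validate_poster(p)
  p
}

#' Validate a poster specification
#'
#' Checks the structural invariants: unique target and marker ids, positive
#' marker sizes, positive assumed distance, at least one target and marker,
#' and that no fixation target lies inside a marker square.
#'
#' @param poster A `poster_spec`.
#' @return The poster, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_poster <- function(poster) {
  if (length(poster$targets) < 1L) stop("poster needs >= 1 target", call. = FALSE)
  if (length(poster$markers) < 1L) stop("poster needs >= 1 marker", call. = FALSE)
  if (!is.finite(poster$assumed_distance) || poster$assumed_distance <= 0) {
    stop("assumed_distance must be > 0", call. = FALSE)
  }
  tids <- vapply(poster$targets, `[[`, integer(1), "id")
  if (anyDuplicated(tids)) {
    stop("duplicate target id: ", tids[duplicated(tids)][1], call. = FALSE)
  }
  mids <- vapply(poster$markers, `[[`, integer(1), "id")
  if (anyDuplicated(mids)) {
    stop("duplicate marker id: ", mids[duplicated(mids)][1], call. = FALSE)
  }
  for (m in poster$markers) {
    if (m$size <= 0) stop("marker ", m$id, ": size must be > 0", call. = FALSE)
  }
  # Markers must not overlap targets: a target point inside a marker square
  # would be unreadable and unfixable.
  for (m in poster$markers) {
    h <- m$size / 2
    th <- m$rotation * pi / 180
    for (t in poster$targets) {
      dx <- t$x - m$center_x
      dy <- t$y - m$center_y
      lx <- cos(th) * dx + sin(th) * dy
      ly <- -sin(th) * dx + cos(th) * dy
      if (abs(lx) <= h && abs(ly) <= h) {
        stop("marker ", m$id, " overlaps target ", t$id, call. = FALSE)
      }
    }
  }
  invisible(poster)
}

#' Default validation poster
#'
#' Nine fixation targets on a 3 x 3 grid sized so that the grid spans
#' 20 degrees horizontally and 17.5 degrees vertically when viewed from a
#' perpendicular distance of 600 mm (outer columns at +/- 600 tan(10 deg) mm,
#' outer rows at +/- 600 tan(8.75 deg) mm). The top-left target is red; the
#' other eight are blue. Sixteen 41.9 mm ArUco markers (ids 0-15, a 4 x 4
#' dictionary) are interleaved with the target grid in four columns and four
#' rows so that the horizontal extent from the left edge of the left-most
#' marker column to the right edge of the right-most column is 356.0 mm — the
#' printed-scale check distance.
#'
#' @param assumed_distance Assumed perpendicular viewing distance, mm.
#' @return A `poster_spec`.
#' @export
default_poster <- function(assumed_distance = 600) {
  deg <- pi / 180
  tx <- assumed_distance * tan(10 * deg)   # half the 20 deg horizontal span
  ty <- assumed_distance * tan(8.75 * deg) # half the 17.5 deg vertical span
  xs <- c(-tx, 0, tx)
  ys <- c(-ty, 0, ty)
  targets <- vector("list", 9L)
  k <- 1L
  for (r in 1:3) {
    for (c in 1:3) {
      targets[[k]] <- target_spec(
        id = k, x = xs[c], y = ys[r],
        appearance = if (k == 1L) "red" else "blue"
      )
      k <- k + 1L
    }
  }
  side <- 41.9
  span <- 356.0
  # Outer marker-column centres sit half a side in from the printed span;
  # four equally spaced columns, and the same spacing for rows.
  outer <- span / 2 - side / 2
  cs <- c(-outer, -outer / 3, outer / 3, outer)
  markers <- vector("list", 16L)
  k <- 1L
  for (r in 1:4) {
    for (c in 1:4) {
      markers[[k]] <- marker_spec(
        id = k - 1L, center_x = cs[c], center_y = cs[r], size = side
      )
      k <- k + 1L
    }
  }
  poster_spec(targets, markers, assumed_distance = assumed_distance)
}

#' Angular span of the target grid from an eye position
#'
#' Horizontal span: the angle between the direction vectors from the eye to
#' the left-most and right-most targets in the row nearest the eye's height
#' (poster y nearest the eye's y). Vertical span analogously, over the column
#' nearest the eye's x. Both are reported in degrees and are non-negative; a
#' single-target poster has zero span.
#'
#' @param poster A `poster_spec`.
#' @param eye Eye position, 3-vector mm in the poster frame (z != 0).
#' @return `c(horizontal = deg, vertical = deg)`.
#' @export
angular_span <- function(poster, eye = c(0, 0, -poster$assumed_distance)) {
  stopifnot(length(eye) == 3)
  if (eye[3] == 0) stop("eye must not lie on the poster plane", call. = FALSE)
  tx <- vapply(poster$targets, `[[`, numeric(1), "x")
  ty <- vapply(poster$targets, `[[`, numeric(1), "y")
  # row nearest eye height
  row_y <- ty[which.min(abs(ty - eye[2]))]
  in_row <- abs(ty - row_y) < 1e-9
  xl <- min(tx[in_row]); xr <- max(tx[in_row])
  hor <- if (xr > xl) {
    angle_between(c(xl, row_y, 0) - eye, c(xr, row_y, 0) - eye)
  } else 0
  col_x <- tx[which.min(abs(tx - eye[1]))]
  in_col <- abs(tx - col_x) < 1e-9
  yt <- min(ty[in_col]); yb <- max(ty[in_col])
  ver <- if (yb > yt) {
    angle_between(c(col_x, yt, 0) - eye, c(col_x, yb, 0) - eye)
  } else 0
  c(horizontal = hor, vertical = ver)
}

#' Nominal horizontal marker span of a poster
#'
#' Distance from the left edge of the left-most marker to the right edge of
#' the right-most marker, mm. This is the distance an operator measures with a
#' ruler to verify print scale.
#'
#' @param poster A `poster_spec`.
#' @return Span in mm.
#' @export
marker_span <- function(poster) {
  lefts <- rights <- numeric(length(poster$markers))
  for (i in seq_along(poster$markers)) {
    cx <- marker_corners_mm(poster$markers[[i]])[, 1]
    lefts[i] <- min(cx); rights[i] <- max(cx)
  }
  max(rights) - min(lefts)
}

#' Check the print scale of a physical poster
#'
#' Printers are frequently miscalibrated; before use, the operator measures
#' the horizontal marker span on the printed sheet and compares it with the
#' nominal span.
#'
#' @param measured_span_mm Measured span, mm (> 0).
#' @param poster A `poster_spec`.
#' @param tolerance Allowed fractional deviation of the scale factor from 1
#'   (default 0.01).
#' @return A list with `scale` (measured / nominal), `pass`, `nominal_mm`
#'   and `measured_mm`.
#' @export
check_print_scale <- function(measured_span_mm, poster = default_poster(),
                              tolerance = 0.01) {
  if (!is.numeric(measured_span_mm) || measured_span_mm <= 0) {
    stop("measured_span_mm must be > 0", call. = FALSE)
  }
  nominal <- marker_span(poster)
  scale <- measured_span_mm / nominal
  list(scale = scale, pass = abs(scale - 1) <= tolerance,
       nominal_mm = nominal, measured_mm = measured_span_mm)
}

#' Poster corner coordinates of a marker
#'
#' Corners in the fixed order top-left, top-right, bottom-right, bottom-left
#' of the (possibly rotated) marker, mm in the poster frame. Detector output
#' is normalised to this order on import.
#'
#' @param marker A `marker_spec`.
#' @return 4 x 2 matrix of (x, y) mm.
#' @export
marker_corners_mm <- function(marker) {
  h <- marker$size / 2
  local <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
  th <- marker$rotation * pi / 180
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  sweep(local %*% t(rot), 2, c(marker$center_x, marker$center_y), `+`)
}

#' Save a poster specification to JSON
#'
#' @param poster A `poster_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_poster <- function(poster, path) {
  tg <- data.frame(
    id = vapply(poster$targets, `[[`, integer(1), "id"),
    x = vapply(poster$targets, `[[`, numeric(1), "x"),
    y = vapply(poster$targets, `[[`, numeric(1), "y"),
    appearance = vapply(poster$targets, `[[`, character(1), "appearance")
  )
  mk <- data.frame(
    id = vapply(poster$markers, `[[`, integer(1), "id"),
    center_x = vapply(poster$markers, `[[`, numeric(1), "center_x"),
    center_y = vapply(poster$markers, `[[`, numeric(1), "center_y"),
    size = vapply(poster$markers, `[[`, numeric(1), "size"),
    rotation = vapply(poster$markers, `[[`, numeric(1), "rotation")
  )
  obj <- list(assumed_distance_mm = poster$assumed_distance,
              paper_size_mm = poster$paper_size,
              targets = tg, markers = mk)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a poster specification from JSON
#'
#' The inverse of [save_poster()]; `load_poster(save_poster(p))` reproduces
#' the geometry exactly. Validation errors (duplicate ids, non-positive
#' sizes, marker/target overlap) name the offending element.
#'
#' @param path JSON file written by [save_poster()] or by hand.
#' @return A `poster_spec`.
#' @export
load_poster <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("targets", "markers", "assumed_distance_mm")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("poster file missing field: ", miss[1], call. = FALSE)
  tg <- obj$targets
  mk <- obj$markers
  targets <- lapply(seq_len(nrow(tg)), function(i) {
    target_spec(tg$id[i], tg$x[i], tg$y[i], tg$appearance[i])
  })
  rot <- if ("rotation" %in% names(mk)) mk$rotation else rep(0, nrow(mk))
  markers <- lapply(seq_len(nrow(mk)), function(i) {
    marker_spec(mk$id[i], mk$center_x[i], mk$center_y[i], mk$size[i], rot[i])
  })
  paper <- if (!is.null(obj$paper_size_mm)) obj$paper_size_mm else c(420, 594)
  poster_spec(targets, markers, assumed_distance = obj$assumed_distance_mm,
              paper_size = paper)
}

#' @export
print.poster_spec <- function(x, ...) {
  cat("<poster_spec> ", length(x$targets), " targets, ", length(x$markers),
      " markers, assumed distance ", x$assumed_distance, " mm\n", sep = "")
  invisible(x)
}

# positions of targets as a matrix (id, x, y), internal convenience
target_positions <- function(poster) {
  cbind(id = vapply(poster$targets, `[[`, integer(1), "id"),
        x = vapply(poster$targets, `[[`, numeric(1), "x"),
        y = vapply(poster$targets, `[[`, numeric(1), "y"))
}
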