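# Facial-activity features from 68-point landmark tracks.
#
# Landmark tracks are tibbles in wide form: one row per frame with column
# `t` (seconds) followed by x0..x67, y0..y67 (0-based point indices) and an
# optional `confidence` column. Point-index groups follow the standard
# 68-point layout: jaw 0-16, right brow 17-21, left brow 22-26, nose 27-35,
# right eye 36-41, left eye 42-47, outer lip 48-59, inner lip 60-67.

landmark_cols <- function() {
  c(paste0("x", 0:67), paste0("y", 0:67))
}

#' Build a landmark track tibble
#'
#' @param t Numeric vector of frame times in seconds (strictly increasing,
#'   uniformly spaced).
#' @param points A numeric array of dimension `c(n_frames, 68, 2)` or a list
#'   of 68 x 2 matrices, one per frame.
#' @param fps Frames per second; checked against the spacing of `t`.
#' @param confidence Optional per-frame detector confidence in \[0, 1\].
#' @return A tibble with columns `t`, `x0..x67`, `y0..y67` and an `fps`
#'   attribute.
#' @export
landmark_track <- function(t, points, fps, confidence = NULL) {
  if (is.list(points)) {
    points <- aperm(simplify2array(points), c(3, 1, 2))
  }
  stopifnot(length(dim(points)) == 3, dim(points)[2] == 68, dim(points)[3] == 2)
  n <- length(t)
  if (dim(points)[1] != n) stop_invalid("`t` and `points` disagree on frame count")
  if (any(!is.finite(points))) stop_invalid("landmark coordinates must be finite")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop_invalid("`t` must be strictly increasing")
    if (any(abs(dt - 1 / fps) > 1e-6)) {
      stop_invalid("`t` must be uniformly spaced at 1/fps")
    }
  }
  out <- as_tibble(setNames(
    c(list(t),
      lapply(1:68, function(j) points[, j, 1]),
      lapply(1:68, function(j) points[, j, 2])),
    c("t", paste0("x", 0:67), paste0("y", 0:67))
  ))
  if (!is.null(confidence)) out$confidence <- confidence
  attr(out, "fps") <- fps
  class(out) <- c("landmark_track", class(out))
  out
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("<landmark_track: %d frames @ %g fps>\n", nrow(x), track_fps(x)))
  NextMethod()
}

track_fps <- function(track) {
  fps <- attr(track, "fps")
  if (is.null(fps)) {
    if (nrow(track) < 2) stop_invalid("track has no fps attribute and a single frame")
    fps <- 1 / stats::median(diff(track$t))
  }
  fps
}

# rows of `track` -> array [n, 68, 2]
track_array <- function(track) {
  cols <- landmark_cols()
  if (!all(cols %in% names(track))) {
    stop_invalid("landmark track must have columns x0..x67, y0..y67")
  }
  n <- nrow(track)
  array(c(as.matrix(track[paste0("x", 0:67)]),
          as.matrix(track[paste0("y", 0:67)])),
        dim = c(n, 68, 2))
}

check_frame <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68 || ncol(points) != 2) {
    stop_invalid("a landmark frame must be a 68 x 2 numeric matrix")
  }
  if (any(!is.finite(points))) stop_invalid("landmark coordinates must be finite")
  points
}

polygon_perimeter <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

polygon_area <- function(pts) {
  # shoelace, absolute value
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:length(x), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Per-frame facial geometry features
#'
#' Scalar geometric descriptors of a single 68-point landmark frame, each a
#' proxy for the activity of a facial muscle group or behaviour:
#'
#' * `mouth_outer()` - closed perimeter of the outer-lip contour (points
#'   48-59), monitoring the zygomatic region (pixels).
#' * `mouth_corner()` - Euclidean distance between the mouth corners,
#'   points 48 and 54 (pixels).
#' * `eye_area()` - sum of the absolute shoelace areas of the two eye
#'   contours (36-41, 42-47); collapses toward 0 during a blink (pixels^2).
#' * `eyebrow_activity()` - distance between the inner eyebrow points 21
#'   and 22; corrugator contraction (frowning) reduces it (pixels).
#' * `face_area()` - convex-hull area of all 68 points; grows as the face
#'   approaches the camera (pixels^2).
#'
#' @param points A 68 x 2 numeric matrix of (x, y) pixel positions,
#'   0-based point indices as described in [landmark_track()].
#' @return A non-negative scalar.
#' @seealso [facial_features()] for the vectorised per-track driver that
#'   also computes the two displacement features.
#' @export
#' @examples
#' mouth_corner(face_template())
mouth_outer <- function(points) {
  points <- check_frame(points)
  polygon_perimeter(points[49:60, , drop = FALSE])
}

#' @rdname mouth_outer
#' @export
mouth_corner <- function(points) {
  points <- check_frame(points)
  sqrt(sum((points[49, ] - points[55, ])^2))
}

#' @rdname mouth_outer
#' @export
eye_area <- function(points) {
  points <- check_frame(points)
  polygon_area(points[37:42, , drop = FALSE]) +
    polygon_area(points[43:48, , drop = FALSE])
}

#' @rdname mouth_outer
#' @export
eyebrow_activity <- function(points) {
  points <- check_frame(points)
  sqrt(sum((points[22, ] - points[23, ])^2))
}

#' @rdname mouth_outer
#' @export
face_area <- function(points) {
  points <- check_frame(points)
  hull <- grDevices::chull(points)
  if (length(hull) < 3) return(0)
  polygon_area(points[hull, , drop = FALSE])
}

#' Per-frame facial-activity feature series F1-F7
#'
#' Computes the seven facial features for every frame of a landmark track:
#' F1 outer-mouth perimeter, F2 mouth-corner distance, F3 total eye area,
#' F4 inner-eyebrow distance, F5 convex-hull face area (see
#' [mouth_outer()] and friends), plus two displacement features that need
#' temporal context:
#'
#' * F6 ("face motion") - trailing 1-second rolling sum, inclusive of the
#'   current frame, of the frame-to-frame displacement of the nose tip
#'   (point 30); total head path length over the last second.
#' * F7 ("facial centre of mass") - displacement of the centroid of all 68
#'   points between consecutive frames.
#'
#' Both F6 and F7 are 0 at the first frame (no predecessor).
#'
#' @param track A landmark track tibble (see [landmark_track()] /
#'   [read_landmarks()]).
#' @return A tibble with columns `t` and `F1`..`F7`, one row per frame.
#' @export
facial_features <- function(track) {
  a <- track_array(track)
  n <- dim(a)[1]
  fps <- track_fps(track)
  # vectorised across frames; identical to the per-frame scalar functions
  pair_dist <- function(i, j) {
    sqrt((a[, i, 1] - a[, j, 1])^2 + (a[, i, 2] - a[, j, 2])^2)
  }
  ring_perimeter <- function(idx) {
    nxt <- c(idx[-1], idx[1])
    Reduce(`+`, Map(pair_dist, idx, nxt))
  }
  ring_area <- function(idx) {
    nxt <- c(idx[-1], idx[1])
    s <- Reduce(`+`, Map(function(i, j) {
      a[, i, 1] * a[, j, 2] - a[, j, 1] * a[, i, 2]
    }, idx, nxt))
    abs(s) / 2
  }
  f1 <- ring_perimeter(49:60)
  f2 <- pair_dist(49, 55)
  f3 <- ring_area(37:42) + ring_area(43:48)
  f4 <- pair_dist(22, 23)
  f5 <- vapply(seq_len(n), function(i) face_area(a[i, , ]), numeric(1))
  # F6: nose-tip (0-based point 30) path length over trailing 1 s
  nose <- a[, 31, , drop = FALSE]
  step <- c(0, sqrt(rowSums((nose[-1, 1, , drop = FALSE] -
                             nose[-n, 1, , drop = FALSE])^2)))
  w <- max(1L, as.integer(round(fps)))
  cs <- cumsum(step)
  lagged <- c(rep(0, w), cs)[seq_len(n)]
  f6 <- cs - lagged
  # F7: centroid displacement between consecutive frames
  if (n == 1) {
    f7 <- 0
  } else {
    centroid <- cbind(rowMeans(matrix(a[, , 1], nrow = n)),
                      rowMeans(matrix(a[, , 2], nrow = n)))
    f7 <- c(0, sqrt(rowSums((centroid[-1, , drop = FALSE] -
                             centroid[-n, , drop = FALSE])^2)))
  }
  tibble(t = track$t, F1 = f1, F2 = f2, F3 = f3, F4 = f4,
         F5 = f5, F6 = f6, F7 = f7)
}

#' Aggregate per-frame features over analysis windows
#'
#' Slow-changing features (F1 mouth perimeter, F2 mouth corners, F5 face
#' area) are aggregated with the window mean; fast-changing features (F3
#' eye area, F4 eyebrows, F6 face motion, F7 centroid displacement) with
#' the population standard deviation (n denominator). Frames with
#' `start <= t < start + length` belong to a window.
#'
#' @param features Per-frame feature tibble from [facial_features()]
#'   (column `t` plus any of `F1`..`F7`).
#' @param windows Window tibble from [analysis_windows()] (columns
#'   `window_start_s`, `window_end_s`).
#' @return A tibble with one row per window: `window_start_s` plus one
#'   column per feature present in `features`.
#' @export
aggregate_features <- function(features, windows) {
  mean_feats <- c("F1", "F2", "F5")
  feat_cols <- intersect(paste0("F", 1:7), names(features))
  if (!length(feat_cols)) stop_invalid("no feature columns F1..F7 in `features`")
  spacing <- if (nrow(features) > 1) stats::median(diff(features$t)) else 0
  if (any(windows$window_start_s < min(features$t) - 1e-9) ||
      any(windows$window_end_s > max(features$t) + spacing + 1e-9)) {
    stop_invalid("a window extends past the feature series")
  }
  purrr::pmap_dfr(
    windows[c("window_start_s", "window_end_s")],
    function(window_start_s, window_end_s) {
      inside <- features$t >= window_start_s - 1e-9 &
        features$t < window_end_s - 1e-9
      if (!any(inside)) {
        stop_invalid(sprintf("window [%g, %g) not covered by feature series",
                             window_start_s, window_end_s))
      }
      vals <- lapply(feat_cols, function(fc) {
        v <- features[[fc]][inside]
        if (fc %in% mean_feats) mean(v) else pop_sd(v)
      })
      as_tibble(setNames(c(list(window_start_s), vals),
                         c("window_start_s", feat_cols)))
    }
  )
}

# population (n-denominator) standard deviation
pop_sd <- function(v) {
  sqrt(mean((v - mean(v))^2))
}
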