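test_that("degenerate frames give zero for every geometric feature", {
  f <- coincident_frame(c(7, 3))
  expect_equal(mouth_outer(f), 0)
  expect_equal(mouth_corner(f), 0)
  expect_equal(eye_area(f), 0)
  expect_equal(eyebrow_activity(f), 0)
  expect_equal(face_area(f), 0)
  # collinear points also give zero areas
  col <- cbind(seq_len(68), 2 * seq_len(68) + 1)
  expect_equal(eye_area(col), 0)
  expect_equal(face_area(col), 0)
})

test_that("malformed frames are rejected", {
  expect_error(mouth_outer(matrix(0, 67, 2)), class = "remoteaffect_invalid_input")
  expect_error(face_area(matrix(Inf, 68, 2)), class = "remoteaffect_invalid_input")
})

test_that("mouth perimeter of a collapsed unit square is 4", {
  # outer-lip points 48..59 visit the four corners of a unit square in
  # order, with repeats; repeated corners contribute zero-length edges
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  f <- frame_with(48:59, corners[rep(1:4, each = 3), ])
  expect_equal(mouth_outer(f), 4)
})

test_that("mouth corner distance follows the Euclidean metric", {
  f <- frame_with(c(48, 54), rbind(c(0, 0), c(3, 4)))
  expect_equal(mouth_corner(f), 5)
  expect_equal(mouth_corner(2.5 * f), 12.5)
})

test_that("eye area is the shoelace sum of the two contours", {
  # one eye on a unit square (with repeated corners), other collapsed
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 1), c(0, 1))
  f <- frame_with(36:41, sq)
  f <- frame_with(42:47, matrix(5, 6, 2), base = f)
  expect_equal(eye_area(f), 1)
})

test_that("eyebrow activity is the inner-brow distance", {
  f <- frame_with(c(21, 22), rbind(c(-1, 0), c(1, 0)))
  expect_equal(eyebrow_activity(f), 2)
  expect_equal(eyebrow_activity(frame_with(c(21, 22), rbind(c(2, 2), c(2, 2)))), 0)
  # a 20% frown reduces the value by exactly 20%
  base <- face_template()
  mid <- colMeans(base[c(22, 23), ])
  frown <- base
  frown[22, ] <- mid + 0.8 * (base[22, ] - mid)
  frown[23, ] <- mid + 0.8 * (base[23, ] - mid)
  expect_equal(eyebrow_activity(frown), 0.8 * eyebrow_activity(base))
})

test_that("template-frame values match independent brute-force oracles", {
  f <- face_template()
  # F1: hand summation of the 12 outer-lip segment lengths
  idx <- 49:60
  per <- 0
  for (k in seq_along(idx)) {
    a <- f[idx[k], ]
    b <- f[idx[if (k == length(idx)) 1 else k + 1], ]
    per <- per + sqrt(sum((a - b)^2))
  }
  expect_equal(mouth_outer(f), per)
  # F5: fan triangulation of the convex hull from its centroid
  hull <- grDevices::chull(f)
  hp <- f[hull, ]
  cen <- colMeans(hp)
  tri <- 0
  for (k in seq_len(nrow(hp))) {
    a <- hp[k, ] - cen
    b <- hp[if (k == nrow(hp)) 1 else k + 1, ] - cen
    tri <- tri + abs(a[1] * b[2] - a[2] * b[1]) / 2
  }
  expect_equal(face_area(f), unname(tri))
})

test_that("features scale linearly (distances) or quadratically (areas)", {
  set.seed(42)
  for (rep in 1:5) {
    f <- face_template() + matrix(rnorm(136, 0, 4), 68, 2)
    k <- runif(1, 0.5, 3)
    expect_equal(mouth_outer(k * f), k * mouth_outer(f))
    expect_equal(mouth_corner(k * f), k * mouth_corner(f))
    expect_equal(eyebrow_activity(k * f), k * eyebrow_activity(f))
    expect_equal(eye_area(k * f), k^2 * eye_area(f))
    expect_equal(face_area(k * f), k^2 * face_area(f), tolerance = 1e-10)
    # translation invariance
    shift <- sweep(f, 2, c(17, -9), `+`)
    expect_equal(mouth_outer(shift), mouth_outer(f))
    expect_equal(eye_area(shift), eye_area(f))
    expect_equal(face_area(shift), face_area(f), tolerance = 1e-10)
  }
})

test_that("face motion F6 is the trailing 1-second nose-tip path length", {
  fps <- 50
  # static track
  tr <- track_from(60, fps, function(i) face_template())
  ff <- facial_features(tr)
  expect_true(all(ff$F6 == 0))
  # nose tip moving 1 px/frame in x: full-second windows sum to 50
  tr2 <- track_from(120, fps, function(i) {
    f <- face_template(); f[31, 1] <- f[31, 1] + i; f
  })
  ff2 <- facial_features(tr2)
  expect_equal(ff2$F6[1], 0)
  expect_true(all(abs(ff2$F6[51:120] - 50) < 1e-9))
  # seeded random walk vs brute-force displacement summation
  set.seed(7)
  steps <- matrix(rnorm(2 * 80), 80, 2)
  pos <- apply(steps, 2, cumsum)
  tr3 <- track_from(80, fps, function(i) {
    f <- face_template(); f[31, ] <- f[31, ] + pos[i, ]; f
  })
  ff3 <- facial_features(tr3)
  d <- c(0, sqrt(rowSums((pos[-1, ] - pos[-80, ])^2)))
  brute <- vapply(seq_len(80), function(i) sum(d[max(1, i - 49):i]), numeric(1))
  expect_equal(ff3$F6, brute)
})

test_that("facial centre of mass F7 tracks centroid displacement only", {
  fps <- 50
  # rigid jump of (3, 4) between two frames
  tr <- track_from(3, fps, function(i) {
    if (i < 3) face_template() else sweep(face_template(), 2, c(3, 4), `+`)
  })
  expect_equal(facial_features(tr)$F7, c(0, 0, 5))
  # antisymmetric deformation: points move but the centroid does not
  tr2 <- track_from(2, fps, function(i) {
    f <- face_template()
    if (i == 2) {
      f[1, ] <- f[1, ] + c(10, 0)
      f[2, ] <- f[2, ] - c(10, 0)
    }
    f
  })
  expect_equal(facial_features(tr2)$F7, c(0, 0))
})

test_that("window aggregation uses mean for F1/F2/F5 and population sd otherwise", {
  w <- tibble::tibble(window_start_s = 0, window_end_s = 2)
  const <- tibble::tibble(t = c(0, 1), F1 = c(3, 3), F3 = c(3, 3))
  agg <- aggregate_features(const, w)
  expect_equal(agg$F1, 3)
  expect_equal(agg$F3, 0)
  two <- tibble::tibble(t = c(0, 1), F1 = c(0, 2), F4 = c(0, 2))
  agg2 <- aggregate_features(two, w)
  expect_equal(agg2$F1, 1)
  expect_equal(agg2$F4, 1) # population sd of {0, 2}
  # seeded series vs an independent two-pass mean/sd oracle
  set.seed(11)
  v <- rnorm(100)
  ser <- tibble::tibble(t = seq(0, 1.98, by = 0.02), F2 = v, F6 = v)
  w2 <- tibble::tibble(window_start_s = 0, window_end_s = 2)
  agg3 <- aggregate_features(ser, w2)
  m <- sum(v) / length(v)
  s2 <- sum((v - m)^2) / length(v)
  expect_equal(agg3$F2, m)
  expect_equal(agg3$F6, sqrt(s2))
})

test_that("mean aggregation of two equal windows equals their average", {
  set.seed(3)
  v <- rnorm(60)
  ser <- tibble::tibble(t = seq(0, 5.9, by = 0.1), F1 = v)
  halves <- aggregate_features(ser, tibble::tibble(
    window_start_s = c(0, 3), window_end_s = c(3, 6)))
  whole <- aggregate_features(ser, tibble::tibble(
    window_start_s = 0, window_end_s = 6))
  expect_equal(mean(halves$F1), whole$F1)
})

test_that("a window extending past the series is a bounds error", {
  ser <- tibble::tibble(t = seq(0, 9.9, by = 0.1), F1 = 1)
  expect_error(
    aggregate_features(ser, tibble::tibble(window_start_s = 5, window_end_s = 30)),
    class = "remoteaffect_invalid_input")
})
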