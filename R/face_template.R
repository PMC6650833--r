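#' Neutral 68-point face template
#'
#' Returns a fixed, synthetic neutral face in the standard 68-point layout
#' (0-based indexing: jaw 0-16, right brow 17-21, left brow 22-26, nose
#' 27-35, right eye 36-41, left eye 42-47, outer lip 48-59, inner lip
#' 60-67). Coordinates are in pixels with the face centred near
#' (320, 240) at a plausible webcam scale; they are arbitrary but frozen,
#' and serve as the base shape for the session simulator and as a test
#' fixture. The y axis points down, as in image coordinates.
#'
#' @return A 68 x 2 numeric matrix with columns `x` and `y`.
#' @export
#' @examples
#' pts <- face_template()
#' dim(pts)
face_template <- function() {
  cx <- 320; cy <- 240
  # jaw: lower half-ellipse, 17 points from right to left
  th <- seq(0, pi, length.out = 17)
  jaw <- cbind(cx + 110 * cos(th), cy - 10 + 130 * sin(th))
  # right brow (subject's right = image left side per iBUG): points 17-21
  bx <- seq(-80, -20, length.out = 5)
  rbrow <- cbind(cx + bx, cy - 62 - 8 * sin(seq(0, pi, length.out = 5)))
  lbrow <- cbind(cx - rev(bx), cy - 62 - 8 * sin(seq(0, pi, length.out = 5)))
  # nose bridge 27-30 + base 31-35
  bridge <- cbind(rep(cx, 4), cy + seq(-45, 10, length.out = 4))
  base <- cbind(cx + seq(-22, 22, length.out = 5),
                cy + c(24, 28, 30, 28, 24))
  eye <- function(ecx) {
    # 6-point contour: outer, top x2, inner, bottom x2 (w=28, h=12)
    cbind(ecx + c(-14, -7, 7, 14, 7, -7),
          cy - 30 + c(0, -6, -6, 0, 6, 6))
  }
  reye <- eye(cx - 50)
  leye <- eye(cx + 50)
  # outer lip 48-59: 12 points around an ellipse (w=60, h=24)
  lth <- seq(pi, 3 * pi, length.out = 13)[-13]
  outer <- cbind(cx + 30 * cos(lth), cy + 72 + 12 * sin(lth))
  # inner lip 60-67: 8 points (w=40, h=8)
  ith <- seq(pi, 3 * pi, length.out = 9)[-9]
  inner <- cbind(cx + 20 * cos(ith), cy + 72 + 4 * sin(ith))
  pts <- rbind(jaw, rbrow, lbrow, bridge, base, reye, leye, outer, inner)
  dimnames(pts) <- list(NULL, c("x", "y"))
  round(pts, 3)
}
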