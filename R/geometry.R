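#' Continuous area moments of a simple polygon
#'
#' Exact (Green's theorem) area, centroid and central second moments of the
#' polygon with the given vertices. Used both to calibrate generated shapes
#' and as a continuum oracle for raster moment computations.
#'
#' @param xy Two-column matrix of vertices `(x, y)`, in order, not repeated.
#' @return List with `area` (positive), `centroid` = c(x, y), and central
#'   second moments `mu20`, `mu11`, `mu02`.
#' @export
polygon_moments <- function(xy) {
  if (!is.matrix(xy) || ncol(xy) != 2 || nrow(xy) < 3) {
    stop_input("xy must be an (n x 2) matrix with n >= 3")
  }
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) stop_input("degenerate polygon")
  s <- sign(a)
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  # second moments about the origin
  iyy <- sum((x^2 + x * x2 + x2^2) * cr) / 12       # integral of x^2 dA
  ixx <- sum((y^2 + y * y2 + y2^2) * cr) / 12       # integral of y^2 dA
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  area <- abs(a)
  list(
    area = area,
    centroid = c(cx, cy),
    mu20 = s * iyy - area * cx^2,
    mu02 = s * ixx - area * cy^2,
    mu11 = s * ixy - area * cx * cy
  )
}

#' Moment-ellipse aspect ratio of a polygon (continuum)
#' @param xy Polygon vertex matrix.
#' @return Aspect ratio sqrt(lambda1/lambda2) >= 1.
#' @keywords internal
polygon_aspect_ratio <- function(xy) {
  m <- polygon_moments(xy)
  cov <- matrix(c(m$mu20, m$mu11, m$mu11, m$mu02), 2, 2) / m$area
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / min(ev))
}

rotate_xy <- function(xy, theta) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy %*% t(r)
}

# scale a centred polygon along its principal axes so that the moment
# aspect ratio becomes `ar` exactly, preserving area
set_polygon_ar <- function(xy, ar) {
  m <- polygon_moments(xy)
  xy <- sweep(xy, 2, m$centroid)
  m <- polygon_moments(xy)
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02)
  xy <- rotate_xy(xy, -theta)
  m <- polygon_moments(xy)
  if (m$mu02 > m$mu20) {                      # put the major axis on x
    xy <- xy[, c(2, 1)]
    xy <- xy[rev(seq_len(nrow(xy))), ]        # keep orientation
    m <- polygon_moments(xy)
  }
  r0 <- sqrt(m$mu20 / m$mu02)
  s <- sqrt(ar / r0)
  cbind(xy[, 1] * s, xy[, 2] / s)
}
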