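shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

conv3 <- function(px, k3) {
  # 3x3 correlation with edge replication; k3 indexed [row offset, col offset]
  out <- matrix(0, nrow(px), ncol(px))
  for (i in -1:1) for (j in -1:1) {
    w <- k3[i + 2, j + 2]
    if (w != 0) out <- out + w * shift_replicate(px, i, j)
  }
  out
}

#' Canny edge detection
#'
#' The classical four-stage detector: Gaussian smoothing, Sobel first
#' derivatives in x (columns) and y (rows), non-maximum suppression along
#' the gradient direction (gradient magnitude sampled on either side of
#' each pixel by bilinear interpolation between the two nearest
#' neighbours, so edges thin to single-pixel chains in any orientation),
#' and double-threshold hysteresis linking (weak edge pixels are kept only
#' in 8-connected chains that contain a strong pixel).
#'
#' @param img A [gray_image] or a numeric/binary matrix.
#' @param sigma Gaussian smoothing standard deviation (> 0).
#' @param low,high Hysteresis thresholds on gradient magnitude,
#'   `0 < low < high`. `NULL` defaults to 10% and 20% of the maximum
#'   gradient magnitude.
#' @return Binary 0/1 integer matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1, low = NULL, high = NULL) {
  px <- if (inherits(img, "gray_image")) img$pixels else {
    stopifnot(is.matrix(img))
    img * 1.0
  }
  if (sigma <= 0) stop_input("sigma must be > 0")
  sm <- local_filter(px, gaussian_kernel_1d(sigma))
  kx <- outer(c(1, 2, 1), c(-1, 0, 1))   # derivative along columns (x)
  ky <- outer(c(-1, 0, 1), c(1, 2, 1))   # derivative along rows (y)
  gx <- conv3(sm, kx)
  gy <- conv3(sm, ky)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0L, nrow(px), ncol(px)))
  high <- high %||% (0.2 * mmax)
  low <- low %||% (0.5 * high)
  if (!(low > 0 && low < high)) stop_input("need 0 < low < high")

  nms <- canny_nms(mag, gx, gy)

  weak <- matrix(as.integer(nms & mag >= low), nrow(px), ncol(px))
  strong <- nms & mag >= high
  if (!any(strong)) return(matrix(0L, nrow(px), ncol(px)))
  labs <- cc_label(weak, 8L)
  keep <- unique(labs[strong])
  keep <- keep[keep > 0L]
  matrix(as.integer(labs %in% keep), nrow(px), ncol(px))
}

# non-maximum suppression with bilinear interpolation of the gradient
# magnitude at +/- one unit step along the gradient direction; the strict
# comparison on the forward side thins plateau ties to single pixels
canny_nms <- function(mag, gx, gy) {
  sgx <- ifelse(gx >= 0, 1L, -1L)
  sgy <- ifelse(gy >= 0, 1L, -1L)
  ax <- abs(gx); ay <- abs(gy)
  sh <- function(dr, dc) shift_replicate(mag, dr, dc)
  pickdir <- function(dr, dc) {
    # value of the neighbour at per-pixel offsets (dr, dc) in {-1,0,1}
    out <- matrix(0, nrow(mag), ncol(mag))
    for (r in sort(unique(as.vector(dr)))) {
      for (c in sort(unique(as.vector(dc)))) {
        sel <- dr == r & dc == c
        if (any(sel)) out[sel] <- sh(r, c)[sel]
      }
    }
    out
  }
  xmajor <- ax >= ay
  w <- ifelse(xmajor, ifelse(ax > 0, ay / pmax(ax, .Machine$double.xmin), 0),
              ax / pmax(ay, .Machine$double.xmin))
  zr <- matrix(0L, nrow(mag), ncol(mag))
  # forward sample: straight neighbour and its diagonal companion
  f_straight <- pickdir(ifelse(xmajor, zr, sgy), ifelse(xmajor, sgx, zr))
  f_diag <- pickdir(sgy, sgx)
  b_straight <- pickdir(ifelse(xmajor, zr, -sgy), ifelse(xmajor, -sgx, zr))
  b_diag <- pickdir(-sgy, -sgx)
  n1 <- (1 - w) * f_straight + w * f_diag
  n2 <- (1 - w) * b_straight + w * b_diag
  mag > n1 & mag >= n2 & mag > 0
}

#' Trace closed outer contours of mask components
#'
#' Labels the 8-connected foreground components of a binary mask and
#' follows the outer boundary of each (Moore neighbour tracing), giving one
#' closed, counter-clockwise contour per component.
#'
#' @param mask Binary 0/1 matrix.
#' @return List of `particle_contour` objects, each with `id`, `vertices`
#'   (ordered (row, col) boundary pixels, first vertex not repeated),
#'   `pixel_idx` (linear indices of the filled region), `dim`, `area_px`,
#'   `perimeter_px` and `touches_border`.
#' @export
trace_contours <- function(mask) {
  assert_mask(mask)
  labs <- cc_label(matrix(as.integer(mask), nrow(mask), ncol(mask)), 8L)
  n <- max(labs)
  if (n == 0L) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  out <- vector("list", n)
  for (id in seq_len(n)) {
    v <- moore_trace(labs, id)
    # counter-clockwise with the y axis (rows) pointing down: positive
    # shoelace area in (x = col, y = -row) coordinates
    x <- v[, 2]; y <- -v[, 1]
    if (nrow(v) >= 3 &&
        sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) {
      v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    }
    idx <- which(labs == id)
    d <- sqrt(diff(c(v[, 1], v[1, 1]))^2 + diff(c(v[, 2], v[1, 2]))^2)
    out[[id]] <- structure(list(
      id = id,
      vertices = v,
      pixel_idx = idx,
      dim = c(nr, nc),
      area_px = length(idx),
      perimeter_px = if (nrow(v) > 1) sum(d) else 0,
      touches_border = any(v[, 1] == 1L | v[, 1] == nr |
                           v[, 2] == 1L | v[, 2] == nc)
    ), class = "particle_contour")
  }
  out
}

#' Filled mask of one contour
#' @param contour A `particle_contour`.
#' @return Binary 0/1 integer matrix of the contour's filled region.
#' @export
contour_mask <- function(contour) {
  m <- matrix(0L, contour$dim[1], contour$dim[2])
  m[contour$pixel_idx] <- 1L
  m
}

# lattice-point count of the convex hull of contour vertices (Pick's
# theorem: points = A + B/2 + 1), commensurate with pixel-count areas
hull_lattice_area <- function(vertices) {
  if (nrow(vertices) < 3) return(nrow(unique(vertices)))
  h <- grDevices::chull(vertices[, 2], vertices[, 1])
  hv <- vertices[h, , drop = FALSE]
  if (nrow(hv) < 3) return(nrow(unique(hv)))
  x <- hv[, 2]; y <- hv[, 1]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  dx <- abs(diff(c(x, x[1]))); dy <- abs(diff(c(y, y[1])))
  b <- sum(mapply(function(p, q) ifelse(p + q == 0, 0,
                                        gcd_int(p, q)), dx, dy))
  a + b / 2 + 1
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Filter out aggregates by convexity, and truncated border particles
#'
#' Aggregated/overlapping convex particles produce a merged silhouette
#' that is concave; isolated convex particles have solidity near 1.
#' Solidity is the filled area divided by the convex-hull area (hull
#' lattice-point count, so a digitally convex region scores exactly 1).
#' Contours touching the image frame are rejected regardless of solidity
#' because their shapes are truncated by the field of view.
#'
#' @param contours List of `particle_contour` (from [trace_contours()]).
#' @param threshold Solidity cutoff in (0, 1]; default 0.96, chosen for
#'   maximal margin between segmented isolated particles (solidity
#'   >= 0.98) and fused pairs (<= 0.95 for near-round shapes).
#' @return List with `kept`, `rejected` (lists of contours) and `verdicts`
#'   (data frame: id, solidity, is_convex, touches_border, kept).
#' @export
convexity_filter <- function(contours, threshold = 0.96) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop_input("threshold must be in (0, 1]")
  }
  n <- length(contours)
  sol <- numeric(n); keep <- logical(n); conv <- logical(n); tb <- logical(n)
  for (i in seq_len(n)) {
    ct <- contours[[i]]
    hull_area <- hull_lattice_area(ct$vertices)
    sol[i] <- min(ct$area_px / hull_area, 1 + 1e-3)
    conv[i] <- sol[i] >= threshold
    tb[i] <- ct$touches_border
    keep[i] <- conv[i] && !tb[i]
  }
  list(
    kept = contours[keep],
    rejected = contours[!keep],
    verdicts = data.frame(
      id = vapply(contours, function(ct) ct$id, integer(1)),
      solidity = sol, is_convex = conv, touches_border = tb, kept = keep
    )
  )
}
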