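#' Configuration for dynamic thresholding and mask cleanup
#'
#' @param window_px Odd local-window side length in pixels (>= 3). A good
#'   default is about four times the expected particle diameter, so the
#'   local statistic reflects background rather than particle interior.
#' @param offset_c Scalar subtracted from the local background statistic to
#'   form the per-pixel threshold. `NULL` (default) estimates it at run
#'   time as twice the robust noise level of the image (median absolute
#'   deviation of the high-pass residual).
#' @param local_statistic `"mean"` (box mean) or `"gaussian_weighted_mean"`.
#' @param min_area_px Connected components smaller than this are removed.
#' @param fill_holes Fill interior holes of each component.
#' @param opening_radius_px Radius of the morphological opening disc
#'   (0 disables opening).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(window_px = 101L,
                             offset_c = NULL,
                             local_statistic = c("gaussian_weighted_mean",
                                                 "mean"),
                             min_area_px = 20L,
                             fill_holes = TRUE,
                             opening_radius_px = 1L) {
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L) {
    stop_input("window_px must be an odd integer >= 3")
  }
  if (min_area_px < 0) stop_input("min_area_px must be >= 0")
  local_statistic <- match.arg(local_statistic)
  structure(list(window_px = window_px, offset_c = offset_c,
                 local_statistic = local_statistic,
                 min_area_px = as.integer(min_area_px),
                 fill_holes = isTRUE(fill_holes),
                 opening_radius_px = as.integer(opening_radius_px)),
            class = "threshold_config")
}

# separable windowed filter with edge-replication padding
local_filter <- function(px, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  rows <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  cols <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  pad <- px[rows, cols]
  out <- stats::filter(pad, kernel, sides = 2)           # down columns
  out <- t(stats::filter(t(out), kernel, sides = 2))     # along rows
  out <- matrix(out, nrow(pad), ncol(pad))
  out[k + seq_len(nr), k + seq_len(nc), drop = FALSE]
}

local_background <- function(px, window_px, statistic) {
  if (statistic == "mean") {
    kernel <- rep(1 / window_px, window_px)
  } else {
    sigma <- window_px / 4
    xs <- seq(-(window_px - 1) / 2, (window_px - 1) / 2)
    kernel <- exp(-xs^2 / (2 * sigma^2))
    kernel <- kernel / sum(kernel)
  }
  local_filter(px, kernel)
}

#' Robust noise estimate of a micrograph
#'
#' Median absolute deviation (scaled to the Gaussian sigma) of the
#' high-pass residual after subtracting a small Gaussian-smoothed copy.
#'
#' @param img A [gray_image] or numeric matrix.
#' @return Estimated noise standard deviation.
#' @export
estimate_noise <- function(img) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  smooth <- local_filter(px, gaussian_kernel_1d(2))
  stats::mad(px - smooth)
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  xs <- seq(-half, half)
  k <- exp(-xs^2 / (2 * sigma^2))
  k / sum(k)
}

#' Global threshold segmentation (baseline)
#'
#' The single-threshold baseline that dynamic thresholding is compared
#' against: it fails when the background intensity varies across the field
#' of view.
#'
#' @param img A [gray_image].
#' @param t Threshold intensity.
#' @return Binary mask (integer matrix of 0/1); foreground is intensity
#'   below `t` for dark particles, above `t` for bright particles.
#' @export
global_threshold <- function(img, t) {
  stopifnot(inherits(img, "gray_image"))
  m <- if (img$polarity == "dark_particles") img$pixels < t else img$pixels > t
  matrix(as.integer(m), nrow(img$pixels), ncol(img$pixels))
}

#' Dynamic (locally adaptive) threshold segmentation
#'
#' Compares each pixel with a local background statistic measured over a
#' sliding window (edge-replicated at the borders), offset by `offset_c`:
#' a dark particle is foreground where its intensity falls below the local
#' statistic minus the offset (sign flipped for bright particles). The raw
#' binary map is then cleaned by [clean_mask()].
#'
#' @param img A [gray_image].
#' @param cfg A [threshold_config].
#' @return Binary mask (integer matrix of 0/1).
#' @export
dynamic_threshold <- function(img, cfg = threshold_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "threshold_config"))
  px <- img$pixels
  if (cfg$window_px >= min(dim(px))) {
    stop_input("window_px must be smaller than the image")
  }
  offset <- cfg$offset_c %||% (2 * estimate_noise(px))
  bg <- local_background(px, cfg$window_px, cfg$local_statistic)
  raw <- if (img$polarity == "dark_particles") px < bg - offset
         else px > bg + offset
  mask <- matrix(as.integer(raw), nrow(px), ncol(px))
  clean_mask(mask, cfg)
}

as_plain_matrix <- function(x, nr, nc) {
  m <- matrix(as.numeric(x), nr, nc)
  m
}

#' Morphological cleanup of a binary mask
#'
#' Applies, in order: opening with a disc brush, hole filling, and removal
#' of connected components (8-connectivity) smaller than `min_area_px`.
#' Idempotent: applying it twice gives the same mask as applying it once.
#'
#' @param mask Binary 0/1 matrix.
#' @param cfg A [threshold_config] (only the cleanup fields are used).
#' @return Cleaned binary 0/1 integer matrix.
#' @export
clean_mask <- function(mask, cfg = threshold_config()) {
  assert_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask
  if (cfg$opening_radius_px > 0 && any(m == 1L)) {
    brush <- EBImage::makeBrush(2L * cfg$opening_radius_px + 1L, "disc")
    m <- as_plain_matrix(EBImage::opening(m, brush), nr, nc)
  }
  if (cfg$fill_holes && any(m == 1L)) {
    m <- as_plain_matrix(EBImage::fillHull(m), nr, nc)
  }
  m <- matrix(as.integer(m > 0.5), nr, nc)
  if (cfg$min_area_px > 0 && any(m == 1L)) {
    labs <- cc_label(m, 8L)
    sizes <- tabulate(labs[labs > 0L])
    drop <- which(sizes < cfg$min_area_px)
    if (length(drop)) m[labs %in% drop] <- 0L
  }
  m
}
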