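#' Central normalized image moments of a filled region
#'
#' Raw moments are sums of `x^p y^q` over foreground pixel centres
#' (0-based coordinates, x = column, y = row), central moments are taken
#' about the centroid, and normalized moments are
#' `eta_pq = mu_pq / mu00^(1 + (p+q)/2)`, which removes the dependence on
#' scale. Computed for all orders `p + q <= 3`.
#'
#' @param region A binary 0/1 matrix, a non-negative weight matrix (e.g.
#'   an anti-aliased coverage raster, giving intensity-weighted moments),
#'   a `particle_contour`, or a two-column matrix of (row, col) foreground
#'   pixel coordinates.
#' @return List with `m00` (area), `centroid` (x, y), central moments `mu`
#'   and normalized moments `eta` (named lists keyed `"pq"`).
#' @export
central_normalized_moments <- function(region) {
  w <- NULL
  if (is.matrix(region) && is.numeric(region) && ncol(region) != 2 &&
      !all(region %in% c(0, 1))) {
    idx <- which(region > 0, arr.ind = TRUE)
    coords <- idx
    w <- region[idx]
  } else {
    coords <- region_coords(region)
    w <- rep(1, nrow(coords))
  }
  if (nrow(coords) == 0) stop_input("region is empty")
  x <- coords[, 2] - 1    # x = column, 0-based
  y <- coords[, 1] - 1    # y = row, 0-based
  m00 <- sum(w)
  cx <- sum(w * x) / m00
  cy <- sum(w * y) / m00
  dx <- x - cx; dy <- y - cy
  mu <- list()
  for (p in 0:3) for (q in 0:3) {
    if (p + q <= 3) mu[[paste0(p, q)]] <- sum(w * dx^p * dy^q)
  }
  eta <- lapply(names(mu), function(k) {
    p <- as.integer(substr(k, 1, 1)); q <- as.integer(substr(k, 2, 2))
    mu[[k]] / m00^(1 + (p + q) / 2)
  })
  names(eta) <- names(mu)
  list(m00 = m00, centroid = c(cx, cy), mu = mu, eta = eta)
}

region_coords <- function(region) {
  if (inherits(region, "particle_contour")) {
    idx <- region$pixel_idx
    nr <- region$dim[1]
    return(cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L))
  }
  if (is.matrix(region) && ncol(region) == 2 && !all(region %in% c(0, 1))) {
    return(region)
  }
  which(region == 1, arr.ind = TRUE)
}

#' The seven Hu moment invariants
#'
#' Polynomial combinations of the normalized central moments that are
#' invariant to translation, scale and rotation (the seventh changes sign
#' under reflection). Also returns the signed-log transform
#' `h_i = -sign(phi_i) * log10(|phi_i|)` (0 when `|phi_i| < 1e-30`), which
#' maps the invariants' wide dynamic range onto comparable scales.
#'
#' @param moments Result of [central_normalized_moments()], or anything it
#'   accepts.
#' @return List with `phi` (numeric length 7) and `log_hu` (numeric
#'   length 7).
#' @export
hu_invariants <- function(moments) {
  if (!is.list(moments) || is.null(moments$eta)) {
    moments <- central_normalized_moments(moments)
  }
  e <- moments$eta
  n20 <- e[["20"]]; n02 <- e[["02"]]; n11 <- e[["11"]]
  n30 <- e[["30"]]; n03 <- e[["03"]]; n21 <- e[["21"]]; n12 <- e[["12"]]
  phi <- numeric(7)
  phi[1] <- n20 + n02
  phi[2] <- (n20 - n02)^2 + 4 * n11^2
  phi[3] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  phi[4] <- (n30 + n12)^2 + (n21 + n03)^2
  phi[5] <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  phi[6] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  phi[7] <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  log_hu <- ifelse(abs(phi) < 1e-30, 0, -sign(phi) * log10(abs(phi)))
  list(phi = phi, log_hu = log_hu)
}

#' Size, aspect ratio and eccentricity of a particle
#'
#' The reported metrology quantities: equivalent-circle diameter
#' `2 * sqrt(area / pi) * nm_per_px` ("the diameter assuming the particle
#' is spherical"), and the moment-ellipse aspect ratio
#' `sqrt(lambda1 / lambda2)` and eccentricity `sqrt(1 - lambda2 / lambda1)`
#' from the eigenvalues `lambda1 >= lambda2` of the second-central-moment
#' matrix. The two satisfy `eccentricity^2 = 1 - 1 / aspect_ratio^2`.
#'
#' @param contour A `particle_contour` (or any region accepted by
#'   [central_normalized_moments()]).
#' @param nm_per_px Calibration in nm per pixel.
#' @return List with `equiv_diameter_nm`, `aspect_ratio`, `eccentricity`,
#'   `centroid_px` (x, y, 0-based) and `degenerate` (TRUE for 1-px-wide
#'   regions whose minor eigenvalue vanishes; such records are excluded
#'   from clustering).
#' @export
metrology <- function(contour, nm_per_px = 1) {
  m <- central_normalized_moments(contour)
  area <- m$m00
  cov <- matrix(c(m$mu[["20"]], m$mu[["11"]],
                  m$mu[["11"]], m$mu[["02"]]), 2, 2) / area
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  l1 <- max(ev); l2 <- min(ev)
  degenerate <- l2 <= .Machine$double.eps * max(l1, 1)
  list(
    equiv_diameter_nm = 2 * sqrt(area / pi) * nm_per_px,
    aspect_ratio = if (degenerate) Inf else sqrt(l1 / l2),
    eccentricity = if (degenerate) 1 else sqrt(1 - l2 / l1),
    centroid_px = m$centroid,
    degenerate = degenerate
  )
}

#' Per-particle shape descriptor table
#'
#' Combines the Hu invariants and the metrology quantities for a set of
#' contours into one data frame (one row per particle), the input to
#' clustering and reporting.
#'
#' @param contours List of `particle_contour`.
#' @param nm_per_px Calibration in nm per pixel.
#' @param solidity Optional per-contour solidity values to carry through.
#' @return Data frame with columns `particle_id`, `phi1..phi7`, `h1..h7`,
#'   `equiv_diameter_nm`, `aspect_ratio`, `eccentricity`, `centroid_x`,
#'   `centroid_y`, `degenerate`.
#' @export
shape_records <- function(contours, nm_per_px = 1, solidity = NULL) {
  n <- length(contours)
  if (n == 0) stop_input("no contours supplied")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- contours[[i]]
    mom <- central_normalized_moments(ct)
    hu <- hu_invariants(mom)
    met <- metrology(ct, nm_per_px)
    rec <- c(list(particle_id = ct$id),
             stats::setNames(as.list(hu$phi), paste0("phi", 1:7)),
             stats::setNames(as.list(hu$log_hu), paste0("h", 1:7)),
             list(equiv_diameter_nm = met$equiv_diameter_nm,
                  aspect_ratio = met$aspect_ratio,
                  eccentricity = met$eccentricity,
                  centroid_x = met$centroid_px[1],
                  centroid_y = met$centroid_px[2],
                  degenerate = met$degenerate))
    rows[[i]] <- as.data.frame(rec)
  }
  out <- do.call(rbind, rows)
  if (!is.null(solidity)) out$solidity <- solidity
  out
}

#' Feature matrix for shape clustering
#'
#' Builds the per-particle feature vectors the shape classes are clustered
#' on. The default is the signed-log Hu vector with two preparation steps
#' that make Euclidean distances meaningful across the invariants' very
#' different magnitudes:
#'
#' * noise-floor masking and clamping: an invariant whose magnitude stays
#'   below `mask_floor` for at least a fraction `mask_prob` of the
#'   particles carries no shape information at the raster resolution (for
#'   symmetric shapes the higher invariants vanish in the continuum, so
#'   their raster values are pure discretization noise, which the log
#'   transform amplifies into dominant, sign-flipping coordinates); such
#'   dimensions are dropped for the whole dataset. In the kept dimensions,
#'   `|phi|` is clamped from below at `mask_floor` before the log, so
#'   sub-noise values map to one bounded point instead of a heavy tail;
#' * standardization: each kept dimension is centred and scaled to unit
#'   variance, so no single invariant dominates the metric.
#'
#' Both steps can be disabled, and the raw invariants are available via
#' `feature = "hu"`.
#'
#' @param records Data frame from [shape_records()].
#' @param feature `"log_hu"` (default) or `"hu"` (raw invariants).
#' @param drop_phi7 Drop the reflection-sensitive seventh invariant.
#' @param mask_floor Noise floor on `|phi|`; `NULL` disables masking.
#' @param mask_prob Fraction of particles that must sit below the floor
#'   for a dimension to be dropped (default 0.9).
#' @param standardize Scale each kept dimension to zero mean and unit
#'   variance (constant dimensions are left centred).
#' @return Numeric matrix (rows = particles); degenerate records are
#'   removed, with the kept row indices in attribute `"row_index"` and the
#'   kept invariant indices in attribute `"dims"`.
#' @export
feature_matrix <- function(records, feature = c("log_hu", "hu"),
                           drop_phi7 = FALSE, mask_floor = 1e-5,
                           mask_prob = 0.9, standardize = TRUE) {
  feature <- match.arg(feature)
  keep <- !records$degenerate
  dims <- if (drop_phi7) 1:6 else 1:7
  phi <- as.matrix(records[keep, paste0("phi", dims), drop = FALSE])
  if (!is.null(mask_floor)) {
    informative <- apply(abs(phi), 2, function(x) {
      stats::quantile(x, mask_prob) >= mask_floor
    })
    informative[1] <- TRUE    # phi1 > 0 for any region; always kept
    dims <- dims[informative]
  }
  if (feature == "hu") {
    m <- as.matrix(records[keep, paste0("phi", dims), drop = FALSE])
  } else if (is.null(mask_floor)) {
    m <- as.matrix(records[keep, paste0("h", dims), drop = FALSE])
  } else {
    ph <- as.matrix(records[keep, paste0("phi", dims), drop = FALSE])
    m <- -sign(ph) * log10(pmax(abs(ph), mask_floor))
    colnames(m) <- paste0("h", dims)
  }
  if (standardize) {
    ctr <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    m <- sweep(sweep(m, 2, ctr), 2, sdv, "/")
  }
  attr(m, "row_index") <- which(keep)
  attr(m, "dims") <- dims
  m
}

#' Hu-invariant stability under rotation, scale and translation
#'
#' Rasterizes a polygon before and after a similarity transform and
#' reports the maximum relative deviation of the first four Hu invariants.
#' Quantifies the (small) rasterization-induced departure from the exact
#' continuum invariance.
#'
#' @param polygon Two-column vertex matrix (x, y) in pixel units.
#' @param rotation Rotation angle in radians.
#' @param scale Scale factor.
#' @param translation Length-2 translation in pixels.
#' @return Maximum over phi1..phi4 of the relative deviation.
#' @export
invariance_check <- function(polygon, rotation = 0, scale = 1,
                             translation = c(0, 0)) {
  phi_a <- hu_invariants(rasterize_polygon(polygon, antialias = TRUE))$phi
  tp <- rotate_xy(polygon, rotation) * scale
  tp <- cbind(tp[, 1] + translation[1], tp[, 2] + translation[2])
  phi_b <- hu_invariants(rasterize_polygon(tp, antialias = TRUE))$phi
  max(abs(phi_b[1:4] - phi_a[1:4]) / pmax(abs(phi_a[1:4]), 1e-12))
}

#' Rasterize a convex polygon to a binary mask
#'
#' @param polygon Two-column (x, y) vertex matrix in pixel units; it is
#'   translated into the positive quadrant automatically.
#' @param pad Margin in pixels around the polygon.
#' @param antialias If `TRUE`, return the subpixel coverage raster
#'   (fractions in `[0, 1]`) instead of a hard 0/1 mask; weighted moments
#'   of the coverage raster track the continuum values much more closely.
#' @return Binary 0/1 integer matrix (pixels with >= 50% coverage), or the
#'   numeric coverage matrix when `antialias = TRUE`.
#' @export
rasterize_polygon <- function(polygon, pad = 3, antialias = FALSE) {
  xy <- cbind(polygon[, 1] - min(polygon[, 1]) + pad,
              polygon[, 2] - min(polygon[, 2]) + pad)
  nc <- ceiling(max(xy[, 1])) + pad + 1
  nr <- ceiling(max(xy[, 2])) + pad + 1
  cov <- convex_coverage(xy, nr, nc, if (antialias) 16L else 4L)
  if (antialias) cov else matrix(as.integer(cov > 0.5), nr, nc)
}
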