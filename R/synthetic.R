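#' Sample a convex particle shape
#'
#' Generates a convex polygon with a prescribed equivalent-circle diameter
#' and moment-ellipse aspect ratio, emulating the particle morphologies seen
#' in TEM projections: regular polygons (hexagonal/pentagonal platelets),
#' rods (rounded rectangles), cubes (squares in projection), and random
#' convex blobs (convex hull of radially perturbed points) for irregular
#' near-round particles.
#'
#' The generated polygon is calibrated exactly: it is rescaled along its
#' principal axes so the continuum moment aspect ratio equals
#' `aspect_ratio`, then isotropically so its area equals that of a circle of
#' diameter `size_nm`.
#'
#' @param family One of `"regular_polygon"`, `"rod"`, `"cube"`,
#'   `"random_convex_blob"`.
#' @param size_nm Equivalent-circle diameter in nm (> 0).
#' @param aspect_ratio Moment-ellipse aspect ratio (>= 1).
#' @param rotation Rotation in radians applied after calibration.
#' @param n_sides Number of sides for `"regular_polygon"` (>= 3).
#' @param nm_per_px Calibration used to convert to pixel units.
#' @return Two-column matrix of vertices `(x, y)` in pixel units, convex,
#'   counter-clockwise; attributes `family`, `size_nm`, `aspect_ratio`.
#'   `random_convex_blob` consumes random numbers from the current RNG
#'   stream.
#' @export
sample_shape <- function(family, size_nm, aspect_ratio = 1, rotation = 0,
                         n_sides = 6, nm_per_px = 1) {
  if (size_nm <= 0) stop_input("size_nm must be > 0")
  if (aspect_ratio < 1) stop_input("aspect_ratio must be >= 1")
  base <- switch(family,
    regular_polygon = {
      if (n_sides < 3) stop_input("n_sides must be >= 3")
      ang <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
      cbind(cos(ang), sin(ang))
    },
    cube = {
      ang <- 2 * pi * (0:3) / 4 + pi / 4
      cbind(cos(ang), sin(ang))
    },
    rod = {
      # stadium: rectangle with semicircular caps, polygonalized
      half_len <- max(aspect_ratio - 1, 0.2)
      t_right <- seq(-pi / 2, pi / 2, length.out = 24)
      t_left <- seq(pi / 2, 3 * pi / 2, length.out = 24)
      rbind(cbind(half_len + cos(t_right), sin(t_right)),
            cbind(-half_len + cos(t_left), sin(t_left)))
    },
    random_convex_blob = {
      m <- 14L
      ang <- sort(stats::runif(m, 0, 2 * pi))
      rad <- 1 + stats::runif(m, -0.3, 0.3)
      pts <- cbind(rad * cos(ang), rad * sin(ang))
      pts[rev(grDevices::chull(pts)), , drop = FALSE]
    },
    stop_input("unknown shape family: ", family)
  )
  xy <- set_polygon_ar(base, aspect_ratio)
  m <- polygon_moments(xy)
  target_area <- pi * (size_nm / 2)^2
  xy <- xy * sqrt(target_area / m$area)
  xy <- rotate_xy(xy, rotation) / nm_per_px
  # enforce counter-clockwise orientation (positive shoelace area)
  x <- xy[, 1]; y <- xy[, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) {
    xy <- xy[rev(seq_len(nrow(xy))), ]
  }
  structure(xy, family = family, size_nm = size_nm,
            aspect_ratio = aspect_ratio)
}

#' Specify a synthetic micrograph scene
#'
#' Describes one synthetic TEM/STEM field of view: the imaging geometry,
#' the particle population (a mixture of shape families with size and
#' aspect-ratio distributions), the packing (including a fraction of
#' particles placed as overlapping aggregate pairs), the background model
#' and the noise level.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param nm_per_px Calibration (nm per pixel).
#' @param polarity `"dark_particles"` (BF-TEM) or `"bright_particles"`
#'   (ADF-STEM).
#' @param shape_mix List of component lists, each with elements `family`,
#'   `fraction`, `size_nm` = c(mean, sd), `aspect_ratio` = c(mean, sd), and
#'   optionally `n_sides`. Fractions must sum to 1.
#' @param n_particles Number of particles to place.
#' @param aggregate_fraction Fraction of particles placed as overlapping
#'   pairs (rounded down to an even count of particles).
#' @param background_model `"flat"`, `"linear_gradient"` or
#'   `"radial_gradient"`.
#' @param background_level Mean background intensity.
#' @param gradient_amplitude Peak-to-trough gradient amplitude as a
#'   fraction of `background_level` (default 0.3, reproducing the uneven
#'   illumination that defeats global thresholding).
#' @param contrast Particle-to-background intensity offset (subtracted for
#'   dark particles, added for bright).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param seed Integer seed driving all stochastic draws.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512L, 512L),
                       nm_per_px = 1,
                       polarity = "dark_particles",
                       shape_mix = list(list(family = "regular_polygon",
                                             fraction = 1,
                                             size_nm = c(34, 2),
                                             aspect_ratio = c(1.0, 0.0),
                                             n_sides = 6)),
                       n_particles = 30L,
                       aggregate_fraction = 0,
                       background_model = "flat",
                       background_level = 160,
                       gradient_amplitude = 0.3,
                       contrast = 70,
                       noise_sigma = 3.5,
                       seed = 1L) {
  fr <- vapply(shape_mix, function(s) s$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop_input("shape_mix fractions must sum to 1")
  if (aggregate_fraction < 0 || aggregate_fraction > 1) {
    stop_input("aggregate_fraction must be in [0, 1]")
  }
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  assert_polarity(polarity)
  if (!background_model %in% c("flat", "linear_gradient", "radial_gradient")) {
    stop_input("unknown background_model: ", background_model)
  }
  structure(list(
    image_size = as.integer(image_size), nm_per_px = nm_per_px,
    polarity = polarity, shape_mix = shape_mix,
    n_particles = as.integer(n_particles),
    aggregate_fraction = aggregate_fraction,
    background_model = background_model,
    background_level = background_level,
    gradient_amplitude = gradient_amplitude,
    contrast = contrast, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# deterministic largest-remainder apportionment of n items to fractions
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

background_field <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  lvl <- spec$background_level
  amp <- spec$gradient_amplitude
  switch(spec$background_model,
    flat = matrix(lvl, h, w),
    linear_gradient = {
      t <- (outer((seq_len(h) - 1) / (h - 1), (seq_len(w) - 1) / (w - 1),
                  `+`)) / 2
      lvl * (1 + amp * (t - 0.5))
    },
    radial_gradient = {
      rr <- (seq_len(h) - (h + 1) / 2) / (h / 2)
      cc <- (seq_len(w) - (w + 1) / 2) / (w / 2)
      rho <- sqrt(outer(rr^2, cc^2, `+`)) / sqrt(2)
      lvl * (1 + amp * (0.5 - rho))
    })
}

#' Render a synthetic micrograph with ground truth
#'
#' Places the requested particle population in the field of view (isolated
#' particles with clearance, aggregated particles as overlapping pairs),
#' rasterizes each convex polygon with subpixel anti-aliasing, composes the
#' scene over the configured background model and adds Gaussian noise.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [scene_spec].
#' @return List with `image` (a [gray_image]) and `truth`, itself a list
#'   with `particles` (data frame: id, family, centroid_row/col px,
#'   equiv_diameter_nm, aspect_ratio, is_aggregated), `labels` (integer
#'   raster of particle ids, 0 = background) and `polygons` (list of vertex
#'   matrices in pixel coordinates).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- spec$n_particles
  fam_counts <- apportion(
    vapply(spec$shape_mix, function(s) s$fraction, numeric(1)), n)
  fam_idx <- sample(rep.int(seq_along(spec$shape_mix), fam_counts))

  n_agg <- (round(n * spec$aggregate_fraction) %/% 2L) * 2L
  is_agg <- rep(FALSE, n)
  if (n_agg > 0) is_agg[seq_len(n_agg)] <- TRUE

  # draw per-particle size / aspect ratio / rotation
  sizes <- numeric(n); ars <- numeric(n); rots <- stats::runif(n, 0, 2 * pi)
  for (i in seq_len(n)) {
    mix <- spec$shape_mix[[fam_idx[i]]]
    sz <- stats::rnorm(1, mix$size_nm[1], mix$size_nm[2])
    sizes[i] <- max(sz, 0.25 * mix$size_nm[1])
    ar <- stats::rnorm(1, mix$aspect_ratio[1], mix$aspect_ratio[2])
    ars[i] <- max(ar, 1.0)
  }
  radii_px <- (sizes / 2) / spec$nm_per_px * sqrt(ars)  # major semi-axis

  centres <- matrix(NA_real_, n, 2)  # (row, col)
  placed <- logical(n)
  clearance <- 4
  place_one <- function(i, partner = NULL) {
    r_i <- radii_px[i]
    for (try in seq_len(500L)) {
      if (is.null(partner)) {
        cand <- c(stats::runif(1, r_i + 2, h - r_i - 1),
                  stats::runif(1, r_i + 2, w - r_i - 1))
        ok_idx <- which(placed)
      } else {
        u <- stats::runif(1, 0.2, 0.5)
        rp <- radii_px[partner]
        d <- r_i + rp - u * min(r_i, rp)
        th <- stats::runif(1, 0, 2 * pi)
        cand <- centres[partner, ] + d * c(sin(th), cos(th))
        if (cand[1] < r_i + 2 || cand[1] > h - r_i - 1 ||
            cand[2] < r_i + 2 || cand[2] > w - r_i - 1) next
        ok_idx <- setdiff(which(placed), partner)
      }
      if (length(ok_idx)) {
        dd <- sqrt((centres[ok_idx, 1] - cand[1])^2 +
                   (centres[ok_idx, 2] - cand[2])^2)
        lim <- radii_px[ok_idx] + r_i + clearance
        if (any(dd < lim)) next
      }
      centres[i, ] <<- cand
      placed[i] <<- TRUE
      return(TRUE)
    }
    FALSE
  }

  order_idx <- seq_len(n)
  i <- 1L
  while (i <= n) {
    if (is_agg[i]) {
      ok <- place_one(i) && place_one(i + 1L, partner = i)
      if (!ok) {
        placed[c(i, i + 1L)] <- FALSE
        stop_input(sprintf(
          "could not place all particles (placed %d of %d); reduce n_particles or enlarge the image",
          sum(placed), n))
      }
      i <- i + 2L
    } else {
      if (!place_one(i)) {
        stop_input(sprintf(
          "could not place all particles (placed %d of %d); reduce n_particles or enlarge the image",
          sum(placed), n))
      }
      i <- i + 1L
    }
  }

  particle_field <- matrix(0, h, w)
  labels <- matrix(0L, h, w)
  polys <- vector("list", n)
  cent_out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    mix <- spec$shape_mix[[fam_idx[i]]]
    poly <- sample_shape(mix$family, sizes[i], ars[i], rots[i],
                         n_sides = mix$n_sides %||% 6L,
                         nm_per_px = spec$nm_per_px)
    # position: vertices in 0-based (x = col, y = row) pixel coordinates
    pxy <- cbind(poly[, 1] + centres[i, 2] - 1, poly[, 2] + centres[i, 1] - 1)
    polys[[i]] <- pxy
    cent_out[i, ] <- centres[i, ]
    cov <- convex_coverage(pxy, h, w, 4L)
    particle_field <- pmax(particle_field, cov)
    sel <- cov > 0.5 & labels == 0L
    labels[sel] <- i
  }

  img <- background_field(spec)
  img <- if (spec$polarity == "dark_particles") {
    img - spec$contrast * particle_field
  } else {
    img + spec$contrast * particle_field
  }
  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  img <- pmax(img, 0)

  truth <- list(
    particles = data.frame(
      id = seq_len(n),
      family = vapply(spec$shape_mix[fam_idx], function(s) s$family,
                      character(1)),
      mix_component = fam_idx,
      centroid_row = cent_out[, 1],
      centroid_col = cent_out[, 2],
      equiv_diameter_nm = sizes,
      aspect_ratio = ars,
      is_aggregated = is_agg,
      stringsAsFactors = FALSE
    ),
    labels = labels,
    polygons = polys
  )
  list(image = gray_image(img, spec$nm_per_px, spec$polarity), truth = truth)
}

#' Preset scenes emulating the three study conditions
#'
#' `"dispersed_polygons_rods"`: a low-magnification bright-field scene of
#' well-dispersed particles, a mixture of hexagonal platelets
#' (34 nm, aspect ratio near 1) and rods (38 nm, aspect ratio near 1.4),
#' over an uneven (linear-gradient) background. `"dense_round"`: a
#' high-packing-density, low-contrast bright-field scene of near-round
#' particles from five shape families. `"dark_field_cubes"`: an ADF-STEM
#' (bright particles) scene of nanocubes with a fraction of touching
#' aggregate pairs.
#'
#' @param case One of the preset names above.
#' @param seed Integer seed.
#' @param n_particles Optionally override the preset particle count.
#' @return A [scene_spec].
#' @export
scene_preset <- function(case = c("dispersed_polygons_rods", "dense_round",
                                  "dark_field_cubes"),
                         seed = 1L, n_particles = NULL) {
  case <- match.arg(case)
  spec <- switch(case,
    dispersed_polygons_rods = scene_spec(
      image_size = c(1024L, 1024L), nm_per_px = 1.0,
      polarity = "dark_particles",
      shape_mix = list(
        list(family = "regular_polygon", fraction = 75 / 156,
             size_nm = c(33.6, 2.0), aspect_ratio = c(1.0, 0.0),
             n_sides = 6L),
        list(family = "rod", fraction = 81 / 156,
             size_nm = c(38.1, 1.7), aspect_ratio = c(1.37, 0.08))
      ),
      n_particles = 156L, aggregate_fraction = 0,
      background_model = "linear_gradient", background_level = 160,
      gradient_amplitude = 0.3, contrast = 70, noise_sigma = 3.5,
      seed = seed),
    dense_round = scene_spec(
      image_size = c(1200L, 1200L), nm_per_px = 0.3,
      polarity = "dark_particles",
      shape_mix = list(
        list(family = "regular_polygon", fraction = 0.2,
             size_nm = c(11.8, 0.7), aspect_ratio = c(1.0, 0.0),
             n_sides = 3L),
        list(family = "cube", fraction = 0.2,
             size_nm = c(11.8, 0.7), aspect_ratio = c(1.0, 0.0)),
        list(family = "rod", fraction = 0.2,
             size_nm = c(11.8, 0.7), aspect_ratio = c(1.4, 0.04)),
        list(family = "rod", fraction = 0.2,
             size_nm = c(11.8, 0.7), aspect_ratio = c(2.0, 0.04)),
        list(family = "rod", fraction = 0.2,
             size_nm = c(11.8, 0.7), aspect_ratio = c(2.8, 0.05))
      ),
      n_particles = 125L, aggregate_fraction = 0,
      background_model = "flat", background_level = 150,
      gradient_amplitude = 0.1, contrast = 30, noise_sigma = 1.5,
      seed = seed),
    dark_field_cubes = scene_spec(
      image_size = c(1024L, 1024L), nm_per_px = 0.25,
      polarity = "bright_particles",
      shape_mix = list(
        list(family = "cube", fraction = 1,
             size_nm = c(10.4, 1.1), aspect_ratio = c(1.06, 0.04))
      ),
      n_particles = 110L, aggregate_fraction = 0.2,
      background_model = "radial_gradient", background_level = 30,
      gradient_amplitude = 0.15, contrast = 120, noise_sigma = 3,
      seed = seed)
  )
  if (!is.null(n_particles)) spec$n_particles <- as.integer(n_particles)
  spec
}

#' Write scene ground truth to plain-text artifacts
#'
#' @param truth The `truth` element of [render_scene()]'s result.
#' @param csv_path Output CSV path for per-particle records.
#' @param label_tiff_path Optional output path for the 16-bit label raster.
#' @return Invisibly, `csv_path`.
#' @export
write_ground_truth <- function(truth, csv_path, label_tiff_path = NULL) {
  utils::write.csv(truth$particles, csv_path, row.names = FALSE)
  if (!is.null(label_tiff_path)) write_label_tiff(truth$labels, label_tiff_path)
  invisible(csv_path)
}

#' Read a scene specification from a YAML config file
#'
#' The file mirrors the arguments of [scene_spec()].
#'
#' @param path YAML file path.
#' @return A [scene_spec].
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scene_spec, cfg)
}
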