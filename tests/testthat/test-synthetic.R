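test_that("generated shapes hit their requested diameter and aspect ratio", {
  set.seed(60)
  cases <- list(
    list(family = "regular_polygon", size = 34, ar = 1.0, n_sides = 6L),
    list(family = "regular_polygon", size = 20, ar = 1.0, n_sides = 5L),
    list(family = "rod", size = 38, ar = 1.4),
    list(family = "rod", size = 12, ar = 2.2),
    list(family = "cube", size = 10.4, ar = 1.06),
    list(family = "random_convex_blob", size = 25, ar = 1.15)
  )
  for (cs in cases) {
    poly <- sample_shape(cs$family, cs$size, cs$ar, rotation = 0.7,
                         n_sides = cs$n_sides %||% 6L, nm_per_px = 0.5)
    m <- polygon_moments(poly)
    d_eq <- 2 * sqrt(m$area / pi) * 0.5
    expect_equal(d_eq, cs$size, tolerance = 0.02)
    expect_equal(nanoshapes:::polygon_aspect_ratio(poly), cs$ar,
                 tolerance = 0.05)
  }
})

test_that("hexagons have moment aspect ratio 1 by symmetry", {
  hexa <- sample_shape("regular_polygon", 34, 1.0, n_sides = 6L)
  expect_equal(nanoshapes:::polygon_aspect_ratio(hexa), 1.0,
               tolerance = 1e-9)
})

test_that("random convex blobs are exactly convex polygons", {
  set.seed(61)
  for (i in 1:10) {
    poly <- sample_shape("random_convex_blob", 30, 1.1)
    hull <- grDevices::chull(poly)
    expect_equal(length(hull), nrow(poly))
  }
})

test_that("shape validation errors", {
  expect_error(sample_shape("regular_polygon", 10, n_sides = 2), "n_sides")
  expect_error(sample_shape("rod", -5), "size_nm")
  expect_error(sample_shape("rod", 5, aspect_ratio = 0.8), "aspect_ratio")
  expect_error(sample_shape("banana", 5), "family")
})

test_that("an empty scene renders the background only", {
  spec <- scene_spec(image_size = c(64L, 64L), n_particles = 0L,
                     noise_sigma = 0, background_model = "flat",
                     background_level = 100, seed = 1)
  sc <- render_scene(spec)
  expect_true(all(sc$image$pixels == 100))
  expect_equal(nrow(sc$truth$particles), 0)
  expect_true(all(sc$truth$labels == 0L))
})

test_that("rendering is bit-identical for a fixed seed", {
  spec <- scene_spec(image_size = c(256L, 256L), n_particles = 8L, seed = 9)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$particles, b$truth$particles)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("aggregate_fraction marks the requested number of particles", {
  spec <- scene_spec(image_size = c(900L, 900L), n_particles = 50L,
                     aggregate_fraction = 0.2, seed = 12,
                     shape_mix = list(list(family = "cube", fraction = 1,
                                           size_nm = c(20, 1),
                                           aspect_ratio = c(1, 0))))
  sc <- render_scene(spec)
  expect_equal(sum(sc$truth$particles$is_aggregated), 10)
})

test_that("midpoint thresholding of a noiseless flat scene recovers truth", {
  spec <- scene_spec(image_size = c(384L, 384L), n_particles = 8L,
                     noise_sigma = 0, background_model = "flat",
                     background_level = 160, contrast = 70, seed = 13)
  sc <- render_scene(spec)
  mask <- global_threshold(sc$image, 160 - 35)
  for (i in seq_len(8)) {
    truth_px <- which(sc$truth$labels == i)
    got_px <- which(mask == 1L)
    inter <- length(intersect(truth_px, got_px))
    # restrict union to the particle's neighbourhood via its own bbox
    iou <- inter / length(truth_px)
    expect_gte(iou, 0.95)
  }
  # overall IoU of the union mask
  t_all <- which(sc$truth$labels > 0); g_all <- which(mask == 1L)
  iou_all <- length(intersect(t_all, g_all)) /
    length(union(t_all, g_all))
  expect_gte(iou_all, 0.95)
})

test_that("polarity flips particle contrast", {
  base <- list(image_size = c(128L, 128L), n_particles = 2L,
               noise_sigma = 0, background_model = "flat",
               background_level = 100, contrast = 50, seed = 4)
  dark <- render_scene(do.call(scene_spec, c(base,
                                             polarity = "dark_particles")))
  bright <- render_scene(do.call(scene_spec, c(base,
                                               polarity = "bright_particles")))
  expect_lt(min(dark$image$pixels), 100)
  expect_gt(max(bright$image$pixels), 100)
})

test_that("shape families are separable in Hu space", {
  set.seed(62)
  feats <- function(family, ar, n = 30) {
    t(replicate(n, {
      poly <- sample_shape(family, runif(1, 30, 40), ar,
                           rotation = runif(1, 0, 2 * pi), n_sides = 6L)
      hu_invariants(rasterize_polygon(poly))$phi[1:2]
    }))
  }
  hexes <- feats("regular_polygon", 1.0)
  rods <- feats("rod", 1.4)
  within_h <- mean(dist(hexes)); within_r <- mean(dist(rods))
  between <- mean(as.matrix(stats::dist(rbind(hexes, rods)))[1:30, 31:60])
  expect_gt(between, max(within_h, within_r))
})

test_that("impossible packings raise a generation error", {
  spec <- scene_spec(image_size = c(128L, 128L), n_particles = 200L,
                     seed = 3)
  expect_error(render_scene(spec), "place")
})

test_that("scene configs round-trip through YAML", {
  spec <- scene_preset("dispersed_polygons_rods", seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(spec), path)
  spec2 <- read_scene_config(path)
  expect_equal(unclass(spec2)[order(names(spec2))],
               unclass(spec)[order(names(spec))], tolerance = 1e-6)
})

test_that("ground truth exports to CSV and label TIFF", {
  sc <- render_scene(scene_spec(image_size = c(128L, 128L),
                                n_particles = 3L, seed = 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  tif <- withr::local_tempfile(fileext = ".tif")
  write_ground_truth(sc$truth, csv, tif)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 3)
  expect_identical(read_label_tiff(tif), sc$truth$labels)
})
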