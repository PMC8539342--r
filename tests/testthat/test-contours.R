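test_that("canny produces no edges on a constant image", {
  img <- gray_image(matrix(100, 32, 32), 1)
  expect_true(all(canny_edges(img, sigma = 1, low = 1, high = 2) == 0L))
})

test_that("canny localizes a vertical step to a 1-px line", {
  px <- matrix(50, 40, 40); px[, 21:40] <- 200
  edges <- canny_edges(gray_image(px, 1), sigma = 1)
  # interior rows: exactly one edge pixel, at the step
  interior <- edges[5:36, ]
  expect_true(all(rowSums(interior) == 1))
  expect_true(all(interior[, 20] == 1L | interior[, 21] == 1L))
})

test_that("canny ring length of a disk is close to its circumference", {
  edges <- canny_edges(disk_mask(40) * 255, sigma = 1.4)
  expect_equal(sum(edges), 2 * pi * 40, tolerance = 0.1)
})

test_that("canny matches the step-by-step reference implementation", {
  # vertical step edge
  px <- matrix(10, 24, 24); px[, 13:24] <- 90
  ref <- oracle_canny(px, sigma = 1, low = 5, high = 15)
  got <- canny_edges(px, sigma = 1, low = 5, high = 15)
  expect_identical(got, ref)
  # small disk
  dm <- disk_mask(8, pad = 4) * 100
  ref2 <- oracle_canny(dm, sigma = 1, low = 10, high = 30)
  got2 <- canny_edges(dm, sigma = 1, low = 10, high = 30)
  expect_identical(got2, ref2)
  expect_error(canny_edges(px, sigma = 1, low = 10, high = 5), "low")
})

test_that("trace_contours handles empty and elementary masks", {
  expect_identical(trace_contours(matrix(0L, 10, 10)), list())
  m <- matrix(0L, 10, 10); m[4:6, 4:6] <- 1L
  cts <- trace_contours(m)
  expect_length(cts, 1)
  expect_equal(nrow(cts[[1]]$vertices), 8)   # 8 boundary pixels of a 3x3
  expect_equal(cts[[1]]$area_px, 9)
  expect_false(cts[[1]]$touches_border)
  expect_false(any(duplicated(cts[[1]]$vertices)))
})

test_that("two disjoint disks give two non-border contours", {
  m <- matrix(0L, 60, 120)
  m[which((row(m) - 30)^2 + (col(m) - 30)^2 <= 12^2)] <- 1L
  m[which((row(m) - 30)^2 + (col(m) - 90)^2 <= 12^2)] <- 1L
  cts <- trace_contours(m)
  expect_length(cts, 2)
  expect_false(any(vapply(cts, function(ct) ct$touches_border, logical(1))))
  # area consistent with filled mask within 1%
  for (ct in cts) {
    expect_equal(ct$area_px, sum(contour_mask(ct)), tolerance = 0.01)
  }
})

test_that("contours are counter-clockwise and touch the border when clipped", {
  m <- matrix(0L, 30, 30)
  m[1:10, 12:20] <- 1L    # clipped at top border
  ct <- trace_contours(m)[[1]]
  expect_true(ct$touches_border)
  v <- ct$vertices
  x <- v[, 2]; y <- -v[, 1]
  shoelace <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(shoelace, 0)
})

test_that("every canny edge pixel lies within 1 px of a traced contour", {
  set.seed(50)
  spec <- scene_spec(image_size = c(256L, 256L), n_particles = 6L,
                     noise_sigma = 0, background_model = "flat", seed = 50)
  sc <- render_scene(spec)
  mask <- matrix(as.integer(sc$truth$labels > 0), 256, 256)
  cts <- trace_contours(mask)
  edges <- which(canny_edges(mask * 255, sigma = 1) == 1L, arr.ind = TRUE)
  verts <- do.call(rbind, lapply(cts, function(ct) ct$vertices))
  for (i in seq_len(nrow(edges))) {
    cheb <- min(pmax(abs(verts[, 1] - edges[i, 1]),
                     abs(verts[, 2] - edges[i, 2])))
    expect_lte(cheb, 1)
  }
})

test_that("convexity filter keeps convex shapes and rejects fused pairs", {
  # disk and square: solidity ~ 1, kept
  cts <- trace_contours(disk_mask(50))
  verd <- convexity_filter(cts)
  expect_gte(verd$verdicts$solidity[1], 0.99)
  expect_length(verd$kept, 1)
  sq <- rect_mask(60, 60)
  verd2 <- convexity_filter(trace_contours(sq))
  expect_gte(verd2$verdicts$solidity[1], 0.99)
  # two fused disks, radius 30, centers 55 px apart: the union's analytic
  # solidity is ~0.91 (union area / hull area with hull = rectangle between
  # centers + two half-disks)
  m <- matrix(0L, 130, 190)
  m[which((row(m) - 65)^2 + (col(m) - 65)^2 <= 30^2)] <- 1L
  m[which((row(m) - 65)^2 + (col(m) - 120)^2 <= 30^2)] <- 1L
  verd3 <- convexity_filter(trace_contours(m))
  r <- 30; d <- 55
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  analytic <- (2 * pi * r^2 - lens) / (d * 2 * r + pi * r^2)
  expect_equal(verd3$verdicts$solidity[1], analytic, tolerance = 0.02)
  expect_lt(verd3$verdicts$solidity[1], 0.95)
  expect_length(verd3$kept, 0)
  expect_length(verd3$rejected, 1)
  # rasterized-hull oracle: count pixels inside the hull of the region
  # (orientation-agnostic: inside iff all edge cross-products share a sign)
  ct <- trace_contours(m)[[1]]
  pts <- ct$vertices
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  in_hull <- function(r0, c0) {
    n <- nrow(hull)
    j <- c(2:n, 1)
    cr <- (hull[j, 2] - hull[, 2]) * (r0 - hull[, 1]) -
          (hull[j, 1] - hull[, 1]) * (c0 - hull[, 2])
    all(cr <= 1e-9) || all(cr >= -1e-9)
  }
  bb <- expand.grid(r0 = min(pts[, 1]):max(pts[, 1]),
                    c0 = min(pts[, 2]):max(pts[, 2]))
  n_in <- sum(mapply(in_hull, bb$r0, bb$c0))
  expect_equal(verd3$verdicts$solidity[1], ct$area_px / n_in,
               tolerance = 0.01)
})

test_that("the filter partitions its input for random scenes", {
  set.seed(51)
  for (s in 1:3) {
    rnd <- clean_mask(matrix(rbinom(80 * 80, 1, 0.3), 80, 80),
                      threshold_config(min_area_px = 8))
    cts <- trace_contours(rnd)
    f <- convexity_filter(cts, 0.9)
    expect_equal(length(f$kept) + length(f$rejected), length(cts))
    expect_true(all(f$verdicts$solidity > 0 &
                    f$verdicts$solidity <= 1 + 1e-3))
  }
})

test_that("threshold validation", {
  expect_error(convexity_filter(list(), threshold = 0), "threshold")
  expect_error(convexity_filter(list(), threshold = 1.2), "threshold")
})
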