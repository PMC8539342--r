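test_that("average linkage agrees with hand agglomeration of {0, 1, 10}", {
  tree <- average_linkage(dist(c(0, 1, 10)))
  expect_equal(tree$merge[1, ], c(-1L, -2L))
  expect_equal(tree$height[1], 1)
  expect_equal(tree$height[2], 9.5)  # mean of d(0,10)=10 and d(1,10)=9
  expect_equal(tree$size, c(2L, 3L))
})

test_that("identical points merge at height zero", {
  tree <- average_linkage(dist(rep(2.5, 6)))
  expect_true(all(tree$height == 0))
  expect_equal(tree$size[5], 6L)
})

test_that("linkage equals the brute-force oracle on random instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:30, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    dmat <- as.matrix(dist(x))
    tree <- average_linkage(dist(x))
    oracle <- oracle_average_linkage(dmat)
    expect_equal(tree$height, oracle$height, tolerance = 1e-12)
    expect_identical(tree$merge, oracle$merge)
  }
})

test_that("linkage heights match stats::hclust average linkage", {
  set.seed(100)
  x <- matrix(rnorm(40 * 4), 40, 4)
  d <- dist(x)
  tree <- average_linkage(d)
  hc <- stats::hclust(d, method = "average")
  expect_equal(tree$height, hc$height, tolerance = 1e-12)
})

test_that("merge heights are non-decreasing (monotone dendrogram)", {
  for (s in 1:5) {
    set.seed(400 + s)
    tree <- average_linkage(dist(matrix(rnorm(60), 20, 3)))
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("cut_linkage produces size-ranked labels at every k", {
  tree <- average_linkage(dist(c(0, 1, 10)))
  expect_identical(cut_linkage(tree, 1), rep(0L, 3))
  expect_identical(sort(cut_linkage(tree, 3)), 0:2)
  lab <- cut_linkage(tree, 2)
  expect_identical(lab, c(0L, 0L, 1L))  # {0,1} is larger, gets id 0
  expect_error(cut_linkage(tree, 0), "k")
  expect_error(cut_linkage(tree, 4), "k")
  # cluster 0 is always the most populous
  set.seed(7)
  x <- c(rnorm(30, 0, 0.1), rnorm(10, 5, 0.1))
  tr2 <- average_linkage(dist(x))
  l2 <- cut_linkage(tr2, 2)
  expect_gte(sum(l2 == 0), sum(l2 == 1))
})

test_that("cut_linkage agrees with stats::cutree partitions", {
  set.seed(41)
  x <- matrix(rnorm(35 * 2), 35, 2)
  d <- dist(x)
  tree <- average_linkage(d)
  hc <- stats::hclust(d, method = "average")
  for (k in c(2, 3, 5, 8)) {
    ours <- cut_linkage(tree, k)
    ref <- stats::cutree(hc, k)
    # same partition up to relabeling
    expect_equal(label_agreement(ours, ref), 1.0)
  }
})

test_that("CVIs reproduce the hand-computed 1-D case {0,1,9,10}", {
  x <- matrix(c(0, 1, 9, 10), 4, 1)
  lab <- c(0, 0, 1, 1)
  d <- dist(x)
  # silhouette: outer points s = 8.5/9.5, inner points s = 7.5/8.5
  expect_equal(silhouette_index(d, lab),
               (2 * 8.5 / 9.5 + 2 * 7.5 / 8.5) / 4, tolerance = 1e-12)
  expect_equal(silhouette_index(d, lab), oracle_silhouette(as.matrix(d), lab),
               tolerance = 1e-12)
  # DB: S = 0.5 each, centroid distance 9
  expect_equal(davies_bouldin_index(x, lab), 1 / 9, tolerance = 1e-12)
  # CH: between = 81, within = 1 -> (81/1)/(1/2)
  expect_equal(calinski_harabasz_index(x, lab), 162, tolerance = 1e-12)
})

test_that("CVIs equal brute-force oracles on random labeled data", {
  for (s in 1:8) {
    set.seed(600 + s)
    n <- sample(12:40, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(0:(k - 1), n, replace = TRUE)
    while (length(unique(lab)) < k) lab <- sample(0:(k - 1), n, replace = TRUE)
    d <- as.matrix(dist(x))
    expect_equal(silhouette_index(d, lab), oracle_silhouette(d, lab),
                 tolerance = 1e-12)
    expect_equal(davies_bouldin_index(x, lab), oracle_davies_bouldin(x, lab),
                 tolerance = 1e-12)
    expect_equal(calinski_harabasz_index(x, lab),
                 oracle_calinski_harabasz(x, lab), tolerance = 1e-12)
  }
})

test_that("CVI edge cases behave as documented", {
  # two coincident-point clusters far apart: silhouette = 1
  x <- matrix(c(0, 0, 9, 9), 4, 1)
  expect_equal(silhouette_index(dist(x), c(0, 0, 1, 1)), 1)
  # two singleton clusters: DB = 0
  expect_equal(davies_bouldin_index(matrix(c(0, 5), 2, 1), c(0, 1)), 0)
  # zero within-cluster scatter: CH = Inf
  expect_identical(calinski_harabasz_index(x, c(0, 0, 1, 1)), Inf)
  expect_error(silhouette_index(dist(x), rep(0, 4)), "k")
  expect_error(davies_bouldin_index(x, c(0, 1, 0, 1)), "coincident")
  # k = n - 1 with one duplicate pair stays finite and matches the oracle
  y <- matrix(c(0, 0, 3, 7), 4, 1)
  lab <- c(0, 0, 1, 2)
  expect_equal(calinski_harabasz_index(y, lab),
               oracle_calinski_harabasz(y, lab), tolerance = 1e-12)
})

test_that("select_k finds two well-separated blobs via common extrema", {
  set.seed(15)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 5, 0.1), 20, 2))
  d <- dist(x)
  tree <- average_linkage(d)
  cvi <- select_k(tree, x, d, k_max = 8)
  expect_equal(cvi$chosen_k, 2L)
  expect_equal(cvi$selection_rule_used, "common_extrema")
})

test_that("select_k finds five well-separated blobs with k_max = 10", {
  set.seed(16)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8, 4, 16), 5, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:5, function(i) {
    sweep(matrix(rnorm(24, 0, 0.2), 12, 2), 2, centers[i, ], `+`)
  }))
  d <- dist(x)
  tree <- average_linkage(d)
  cvi <- select_k(tree, x, d, k_max = 10)
  expect_equal(cvi$chosen_k, 5L)
})

test_that("structureless data exercises a fallback selection rule", {
  set.seed(17)
  hit_fallback <- FALSE
  for (s in 1:10) {
    x <- matrix(runif(60), 30, 2)
    d <- dist(x)
    cvi <- select_k(average_linkage(d), x, d, k_max = 8)
    if (cvi$selection_rule_used != "common_extrema") hit_fallback <- TRUE
  }
  expect_true(hit_fallback)
})

test_that("input order only relabels the clustering", {
  set.seed(18)
  x <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 6, 0.3), 15, 2))
  perm <- sample(nrow(x))
  d1 <- dist(x); d2 <- dist(x[perm, ])
  l1 <- select_k(average_linkage(d1), x, d1, 6)$labels
  l2 <- select_k(average_linkage(d2), x[perm, ], d2, 6)$labels
  expect_equal(label_agreement(l1[perm], l2), 1.0)
})

test_that("degenerate inputs are rejected", {
  expect_error(average_linkage(dist(5)), "2")
  tree <- average_linkage(dist(c(0, 1, 2, 3, 10)))
  expect_error(select_k(tree, matrix(0:4, 5, 1), dist(0:4), k_max = 2), "k_max")
})
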