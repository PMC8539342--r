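#' Per-cluster summary table
#'
#' The metrology summary reported for each shape class: particle count,
#' fraction of kept particles, and mean +/- sd of equivalent diameter,
#' aspect ratio and eccentricity. Rows are ordered by descending count
#' (cluster k0 is the most populous). The sd is the population standard
#' deviation by default.
#'
#' @param records Data frame from [shape_records()].
#' @param labels Integer cluster labels aligned with `records` rows.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return Data frame with columns `cluster`, `count`, `rate`,
#'   `size_mean`, `size_sd`, `aspect_ratio_mean`, `aspect_ratio_sd`,
#'   `eccentricity_mean`, `eccentricity_sd`.
#' @export
summarize_clusters <- function(records, labels,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(records) == 0) stop_input("no records to summarize")
  if (length(labels) != nrow(records)) {
    stop_input("labels must align with records")
  }
  sdev <- function(x) {
    if (length(x) == 1) return(0)
    s2 <- stats::var(x)
    if (sd_type == "population") sqrt(s2 * (length(x) - 1) / length(x))
    else sqrt(s2)
  }
  n <- nrow(records)
  ids <- sort(unique(labels))
  rows <- lapply(ids, function(g) {
    r <- records[labels == g, ]
    data.frame(
      cluster = g, count = nrow(r), rate = nrow(r) / n,
      size_mean = mean(r$equiv_diameter_nm),
      size_sd = sdev(r$equiv_diameter_nm),
      aspect_ratio_mean = mean(r$aspect_ratio),
      aspect_ratio_sd = sdev(r$aspect_ratio),
      eccentricity_mean = mean(r$eccentricity),
      eccentricity_sd = sdev(r$eccentricity)
    )
  })
  out <- do.call(rbind, rows)
  out[order(-out$count, out$cluster), , drop = FALSE]
}

#' Per-cluster histogram data
#'
#' Left-closed, right-open bins (`[left, left + width)`) anchored at
#' `floor(min / width) * width`, counted separately per cluster. Bin totals
#' conserve the number of records.
#'
#' @param records Data frame from [shape_records()].
#' @param labels Cluster labels aligned with `records`.
#' @param field `"equiv_diameter_nm"`, `"aspect_ratio"` or
#'   `"eccentricity"`.
#' @param bin_width Bin width (> 0); defaults per field: 1 nm for size,
#'   0.05 for aspect ratio and eccentricity.
#' @return Tidy data frame: `cluster`, `bin_left`, `count`.
#' @export
histogram_data <- function(records, labels,
                           field = c("equiv_diameter_nm", "aspect_ratio",
                                     "eccentricity"),
                           bin_width = NULL) {
  field <- match.arg(field)
  bin_width <- bin_width %||%
    switch(field, equiv_diameter_nm = 1, aspect_ratio = 0.05,
           eccentricity = 0.05)
  if (bin_width <= 0) stop_input("bin_width must be > 0")
  x <- records[[field]]
  left <- floor(x / bin_width) * bin_width
  agg <- stats::aggregate(list(count = x),
                          by = list(cluster = labels, bin_left = left),
                          FUN = length)
  agg <- agg[order(agg$cluster, agg$bin_left), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Best-permutation agreement between two labelings
#'
#' The maximum, over all one-to-one matchings of cluster ids, of the
#' fraction of items assigned matching labels: the score used to compare
#' automatic against manual classification. Symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length label vectors (at most 10
#'   distinct values in the smaller set).
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_input("labelings must have the same length")
  }
  ids_a <- unique(labels_a); ids_b <- unique(labels_b)
  if (length(ids_a) > 10 || length(ids_b) > 10) {
    stop_input("label_agreement supports at most 10 clusters")
  }
  conf <- table(factor(labels_a, levels = ids_a),
                factor(labels_b, levels = ids_b))
  best <- best_assignment(unclass(conf))
  best / length(labels_a)
}

# maximum-sum one-to-one assignment by depth-first search with a greedy
# upper bound (exhaustive over permutations; k <= 10 keeps this trivial)
best_assignment <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr > nc) return(best_assignment(t(m)))
  colmax <- apply(m, 2, max)
  best <- 0
  used <- rep(FALSE, nc)
  recurse <- function(row, acc) {
    if (row > nr) { best <<- max(best, acc); return() }
    avail <- sort(colmax[!used], decreasing = TRUE)
    take <- min(nr - row + 1, length(avail))
    if (acc + sum(avail[seq_len(take)]) <= best) return()
    for (cc in seq_len(nc)) {
      if (!used[cc]) {
        used[cc] <<- TRUE
        recurse(row + 1, acc + m[row, cc])
        used[cc] <<- FALSE
      }
    }
  }
  recurse(1, 0)
  best
}

#' Render a classification or filtering overlay
#'
#' Writes a color PNG of the micrograph with contour boundary pixels
#' recolored: one distinct color per cluster in classification mode, or
#' kept/rejected two-tone in filtering mode.
#'
#' @param img A [gray_image].
#' @param contours List of `particle_contour`.
#' @param labels Integer cluster ids per contour, or a logical vector
#'   (TRUE = kept) for filtering mode, or `NULL` for no coloring.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
render_overlay <- function(img, contours, labels = NULL, path) {
  stopifnot(inherits(img, "gray_image"))
  px <- img$pixels
  rng <- range(px)
  g <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  rgb <- array(rep(g, 3), c(nrow(px), ncol(px), 3))
  if (length(contours)) {
    if (is.null(labels)) labels <- rep(0L, length(contours))
    if (is.logical(labels)) {
      pal <- matrix(c(1, 0.85, 0, 0.45, 0.45, 0.45), 2, 3, byrow = TRUE)
      cols <- ifelse(labels, 1L, 2L)  # kept = yellow, rejected = grey
    } else {
      base <- grDevices::col2rgb(grDevices::hcl.colors(
        max(labels) + 1L, "Dark 3")) / 255
      pal <- t(base)
      cols <- labels + 1L
    }
    for (i in seq_along(contours)) {
      v <- contours[[i]]$vertices
      for (ch in 1:3) {
        rgb[cbind(v[, 1], v[, 2], ch)] <- pal[cols[i], ch]
      }
    }
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}
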