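#' Average-linkage agglomerative clustering
#'
#' Builds the full merge hierarchy: at each step the pair of clusters with
#' the smallest average pairwise inter-cluster distance
#' `d(A,B) = mean over a in A, b in B of d(a,b)` is merged (UPGMA).
#' Ties are broken deterministically by the lexicographically smallest
#' pair of cluster identifiers, where a cluster is identified by its
#' smallest member index. Average linkage on a metric input yields
#' non-decreasing merge heights.
#'
#' @param dist A `dist` object or a symmetric distance matrix.
#' @return Object of class `linkage_tree`: list with `n`, `merge`
#'   (hclust-style: negative entries are leaves), `height`, `size`
#'   (cluster size after each merge).
#' @export
average_linkage <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2) stop_input("need at least 2 items")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop_input("distances must be non-negative with zero diagonal")
  }
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  minmem <- seq_len(n)           # smallest original member of each cluster
  node <- -seq_len(n)            # hclust coding: negative leaf, positive merge
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  msize <- integer(n - 1)
  diag(d) <- Inf
  d[!active, ] <- Inf
  for (step in seq_len(n - 1)) {
    dm <- d
    dm[!active, ] <- Inf
    dm[, !active] <- Inf
    best <- min(dm)
    # candidate pairs at the minimum; deterministic lexicographic tie-break
    idx <- which(dm <= best + 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    key_a <- pmin(minmem[idx[, 1]], minmem[idx[, 2]])
    key_b <- pmax(minmem[idx[, 1]], minmem[idx[, 2]])
    pick <- order(key_a, key_b)[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]
    if (minmem[i] > minmem[j]) { t <- i; i <- j; j <- t }
    merge[step, ] <- c(node[i], node[j])
    height[step] <- best
    msize[step] <- sizes[i] + sizes[j]
    # Lance-Williams update for average linkage
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others)) {
      d[i, others] <- (sizes[i] * d[i, others] + sizes[j] * d[j, others]) /
        (sizes[i] + sizes[j])
      d[others, i] <- d[i, others]
    }
    sizes[i] <- sizes[i] + sizes[j]
    minmem[i] <- min(minmem[i], minmem[j])
    node[i] <- step
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
  }
  structure(list(n = n, merge = merge, height = height, size = msize),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %d merges, heights [%.4g, %.4g]\n",
              x$n, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' Removes the `k - 1` highest merges and labels the resulting clusters
#' `0 .. k-1` by decreasing cluster size, ties by smallest first-member
#' index (so cluster 0 is always the most populous).
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster ids `0 .. k-1`, one per leaf.
#' @export
cut_linkage <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n
  if (k < 1 || k > n) stop_input("k must be in 1..n")
  lab <- seq_len(n)
  # apply the first n-k merges (they are in non-decreasing height order)
  nsteps <- n - k
  cluster_of_node <- integer(nsteps)  # cluster id for positive merge nodes
  for (s in seq_len(nsteps)) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ca <- if (a < 0) lab[-a] else cluster_of_node[a]
    cb <- if (b < 0) lab[-b] else cluster_of_node[b]
    keep <- min(ca, cb)
    lab[lab == ca | lab == cb] <- keep
    cluster_of_node[s] <- keep
  }
  # relabel by decreasing size, ties by first member
  ids <- unique(lab)
  size <- vapply(ids, function(i) sum(lab == i), integer(1))
  first <- vapply(ids, function(i) which(lab == i)[1], integer(1))
  ord <- ids[order(-size, first)]
  match(lab, ord) - 1L
}

#' Silhouette index
#'
#' Mean over items of `(b - a) / max(a, b)`, where `a` is the mean
#' distance to the item's own cluster (0 by convention for singletons,
#' giving the item silhouette 0) and `b` the smallest mean distance to
#' another cluster. Larger is better; range `[-1, 1]`.
#'
#' @param dist `dist` object or symmetric matrix.
#' @param labels Cluster labels (any values; `k >= 2` non-empty clusters).
#' @return Mean silhouette width.
#' @export
silhouette_index <- function(dist, labels) {
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  ids <- unique(labels)
  if (length(ids) < 2) stop_input("silhouette requires k >= 2")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(ids[ids != labels[i]],
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) sum_i max_{j != i} (S_i + S_j) / M_ij`, with `S_i` the mean
#' distance of members to their cluster centroid and `M_ij` the distance
#' between centroids. Smaller is better.
#'
#' @param features Numeric feature matrix (rows = items).
#' @param labels Cluster labels.
#' @return The index value.
#' @export
davies_bouldin_index <- function(features, labels) {
  features <- as.matrix(features)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2) stop_input("Davies-Bouldin requires k >= 2")
  cent <- matrix(0, k, ncol(features))
  for (ii in seq_len(k)) {
    cent[ii, ] <- colMeans(features[labels == ids[ii], , drop = FALSE])
  }
  spread <- vapply(seq_len(k), function(ii) {
    x <- features[labels == ids[ii], , drop = FALSE]
    mean(sqrt(rowSums((x - matrix(cent[ii, ], nrow(x), ncol(x),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  r <- numeric(k)
  for (ii in seq_len(k)) {
    vals <- vapply(setdiff(seq_len(k), ii), function(jj) {
      m <- sqrt(sum((cent[ii, ] - cent[jj, ])^2))
      if (m == 0) stop_input("coincident cluster centroids")
      (spread[ii] + spread[jj]) / m
    }, numeric(1))
    r[ii] <- max(vals)
  }
  mean(r)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster scatter,
#' `CH = [B / (k-1)] / [W / (n-k)]`. Larger is better; `+Inf` when the
#' within-cluster scatter is exactly zero.
#'
#' @inheritParams davies_bouldin_index
#' @return The index value (possibly `Inf`).
#' @export
calinski_harabasz_index <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2 || k > n - 1) stop_input("Calinski-Harabasz requires 2 <= k <= n-1")
  grand <- colMeans(features)
  between <- 0; within <- 0
  for (g in ids) {
    x <- features[labels == g, , drop = FALSE]
    cg <- colMeans(x)
    between <- between + nrow(x) * sum((cg - grand)^2)
    within <- within + sum(sweep(x, 2, cg)^2)
  }
  if (within == 0) {
    if (between == 0) stop_input("degenerate clustering: zero scatter")
    return(Inf)
  }
  (between / (k - 1)) / (within / (n - k))
}

local_extrema <- function(x, maximize) {
  v <- if (maximize) x else -x
  n <- length(v)
  if (n == 1) return(1L)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- if (i > 1) v[i - 1] else -Inf
    hi <- if (i < n) v[i + 1] else -Inf
    out[i] <- v[i] >= lo && v[i] >= hi && (v[i] > lo || v[i] > hi)
  }
  # endpoints count when they beat their single neighbour
  if (n >= 2) {
    out[1] <- v[1] > v[2]
    out[n] <- v[n] > v[n - 1]
  }
  which(out)
}

#' Select the number of shape clusters from three validity indexes
#'
#' Evaluates Silhouette, Davies-Bouldin and Calinski-Harabasz for every
#' cut `k = 2 .. k_max` of the linkage tree. The chosen `k` is the
#' smallest one at a common local extremum of all three indexes (maxima
#' for Silhouette and CH, minima for DB; an endpoint of the range counts
#' as an extremum when it beats its single neighbour). If the three sets
#' share no `k`, the smallest `k` in at least two sets is used
#' (`"majority"`); failing that, the global Silhouette maximum
#' (`"silhouette_fallback"`). The rule actually used is recorded.
#'
#' @param tree A `linkage_tree`.
#' @param features Feature matrix the tree was built on.
#' @param dist Matching `dist` object (or matrix).
#' @param k_max Largest k to evaluate (default 10).
#' @return Object of class `cvi_profile`: data frame `profile` (k,
#'   silhouette, davies_bouldin, calinski_harabasz), `chosen_k`,
#'   `selection_rule_used`, and `labels` for the chosen cut.
#' @export
select_k <- function(tree, features, dist, k_max = 10L) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n
  k_max <- as.integer(min(k_max, n - 1L))
  if (k_max < 3L) stop_input("need k_max >= 3 and n >= k_max + 1")
  ks <- 2:k_max
  sil <- db <- ch <- numeric(length(ks))
  labs_all <- vector("list", length(ks))
  for (ii in seq_along(ks)) {
    lab <- cut_linkage(tree, ks[ii])
    labs_all[[ii]] <- lab
    sil[ii] <- silhouette_index(dist, lab)
    db[ii] <- tryCatch(davies_bouldin_index(features, lab),
                       error = function(e) NA_real_)
    ch[ii] <- tryCatch(calinski_harabasz_index(features, lab),
                       error = function(e) NA_real_)
  }
  ext_sil <- ks[local_extrema(sil, maximize = TRUE)]
  ext_db <- ks[local_extrema(ifelse(is.na(db), Inf, db), maximize = FALSE)]
  ext_ch <- ks[local_extrema(ifelse(is.na(ch), -Inf, ch), maximize = TRUE)]
  common <- intersect(intersect(ext_sil, ext_db), ext_ch)
  if (length(common)) {
    chosen <- min(common); rule <- "common_extrema"
  } else {
    pairs <- sort(c(intersect(ext_sil, ext_db), intersect(ext_sil, ext_ch),
                    intersect(ext_db, ext_ch)))
    if (length(pairs)) {
      chosen <- min(pairs); rule <- "majority"
    } else {
      chosen <- ks[which.max(sil)]; rule <- "silhouette_fallback"
    }
  }
  structure(list(
    profile = data.frame(k = ks, silhouette = sil, davies_bouldin = db,
                         calinski_harabasz = ch),
    chosen_k = chosen,
    selection_rule_used = rule,
    labels = labs_all[[match(chosen, ks)]]
  ), class = "cvi_profile")
}

#' @export
print.cvi_profile <- function(x, ...) {
  cat(sprintf("<cvi_profile> chosen_k = %d (rule: %s)\n", x$chosen_k,
              x$selection_rule_used))
  print(x$profile, row.names = FALSE)
  invisible(x)
}
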