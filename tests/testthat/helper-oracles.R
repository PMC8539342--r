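# Independent brute-force oracles and fixture builders. These deliberately
# use the most direct formulation of each definition (loops, exhaustive
# enumeration) and share no code with the implementation they check.

disk_mask <- function(radius, pad = 6) {
  side <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- outer(seq_len(side), seq_len(side),
             function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
  matrix(as.integer(m), side, side)
}

rect_mask <- function(height, width, pad = 6) {
  m <- matrix(0L, height + 2 * pad, width + 2 * pad)
  m[pad + seq_len(height), pad + seq_len(width)] <- 1L
  m
}

# naive O(n^3) average-linkage agglomeration, recomputing every
# inter-cluster average from the original distances at each step
oracle_average_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  node_id <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        key_new <- c(min(min(clusters[[i]]), min(clusters[[j]])),
                     max(min(clusters[[i]]), min(clusters[[j]])))
        if (d < best - 1e-14) {
          best <- d; bi <- i; bj <- j; bkey <- key_new
        } else if (abs(d - best) <= 1e-14) {
          if (key_new[1] < bkey[1] ||
              (key_new[1] == bkey[1] && key_new[2] < bkey[2])) {
            bi <- i; bj <- j; bkey <- key_new
          }
        }
      }
    }
    a <- node_id[bi]; b <- node_id[bj]
    if (min(clusters[[bi]]) > min(clusters[[bj]])) { t <- a; a <- b; b <- t }
    merges[step, ] <- c(a, b)
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    node_id[bi] <- step
    clusters[[bj]] <- NULL
    node_id <- node_id[-bj]
  }
  list(merge = merges, height = heights)
}

oracle_silhouette <- function(dmat, labels) {
  n <- nrow(dmat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(dmat[i, same])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dmat[i, which(labels == g)]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(x, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  cent <- lapply(ids, function(g) colMeans(x[labels == g, , drop = FALSE]))
  sp <- vapply(seq_len(k), function(i) {
    xi <- x[labels == ids[i], , drop = FALSE]
    mean(apply(xi, 1, function(row) sqrt(sum((row - cent[[i]])^2))))
  }, numeric(1))
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      m <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (sp[i] + sp[j]) / m)
    }
    total <- total + worst
  }
  total / k
}

oracle_calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  ids <- sort(unique(labels))
  k <- length(ids)
  grand <- colMeans(x)
  b <- 0; w <- 0
  for (g in ids) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    b <- b + nrow(xg) * sum((cg - grand)^2)
    for (r in seq_len(nrow(xg))) w <- w + sum((xg[r, ] - cg)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# pixel-by-pixel reference Canny for tiny images: same definition,
# written as plain loops
oracle_canny <- function(px, sigma, low, high) {
  nr <- nrow(px); nc <- ncol(px)
  half <- max(1L, ceiling(3 * sigma))
  ker <- exp(-(-half:half)^2 / (2 * sigma^2)); ker <- ker / sum(ker)
  at <- function(m, r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
  sm <- matrix(0, nr, nc)
  tmp <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    acc <- 0
    for (t in -half:half) acc <- acc + ker[t + half + 1] * at(px, r + t, c)
    tmp[r, c] <- acc
  }
  for (r in 1:nr) for (c in 1:nc) {
    acc <- 0
    for (t in -half:half) acc <- acc + ker[t + half + 1] * at(tmp, r, c + t)
    sm[r, c] <- acc
  }
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  sob_s <- c(1, 2, 1); sob_d <- c(-1, 0, 1)
  for (r in 1:nr) for (c in 1:nc) {
    ax <- 0; ay <- 0
    for (i in -1:1) for (j in -1:1) {
      v <- at(sm, r + i, c + j)
      ax <- ax + sob_s[i + 2] * sob_d[j + 2] * v
      ay <- ay + sob_d[i + 2] * sob_s[j + 2] * v
    }
    gx[r, c] <- ax; gy[r, c] <- ay
  }
  mag <- sqrt(gx^2 + gy^2)
  nms <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    m0 <- mag[r, c]
    if (m0 <= 0) next
    axv <- abs(gx[r, c]); ayv <- abs(gy[r, c])
    sx <- if (gx[r, c] >= 0) 1 else -1
    sy <- if (gy[r, c] >= 0) 1 else -1
    if (axv >= ayv) {
      w <- if (axv > 0) ayv / axv else 0
      n1 <- (1 - w) * at(mag, r, c + sx) + w * at(mag, r + sy, c + sx)
      n2 <- (1 - w) * at(mag, r, c - sx) + w * at(mag, r - sy, c - sx)
    } else {
      w <- axv / ayv
      n1 <- (1 - w) * at(mag, r + sy, c) + w * at(mag, r + sy, c + sx)
      n2 <- (1 - w) * at(mag, r - sy, c) + w * at(mag, r - sy, c - sx)
    }
    nms[r, c] <- m0 > n1 && m0 >= n2
  }
  weak <- nms & mag >= low
  strong <- nms & mag >= high
  # hysteresis by repeated dilation of strong within weak
  cur <- strong
  repeat {
    grown <- cur
    for (r in 1:nr) for (c in 1:nc) {
      if (!weak[r, c] || cur[r, c]) next
      for (i in -1:1) for (j in -1:1) {
        rr <- r + i; cc <- c + j
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && cur[rr, cc]) {
          grown[r, c] <- TRUE
        }
      }
    }
    if (identical(grown, cur)) break
    cur <- grown
  }
  matrix(as.integer(cur), nr, nc)
}

# brute-force local-mean threshold with edge replication
oracle_local_mean_mask <- function(px, window, offset) {
  nr <- nrow(px); nc <- ncol(px)
  k <- (window - 1) / 2
  out <- matrix(0L, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    rs <- pmin(pmax((r - k):(r + k), 1), nr)
    cs <- pmin(pmax((c - k):(c + k), 1), nc)
    if (px[r, c] < mean(px[rs, cs]) - offset) out[r, c] <- 1L
  }
  out
}

# IoU of best-matching traced contour against one truth region
best_iou <- function(truth_idx, contours) {
  best <- 0
  for (ct in contours) {
    inter <- length(intersect(truth_idx, ct$pixel_idx))
    uni <- length(truth_idx) + length(ct$pixel_idx) - inter
    best <- max(best, inter / uni)
  }
  best
}

# map each record to the nearest ground-truth particle by centroid
truth_match <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i) {
    which.min((truth$centroid_col - 1 - records$centroid_x[i])^2 +
              (truth$centroid_row - 1 - records$centroid_y[i])^2)
  }, integer(1))
}
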