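# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: per-pixel distance scans, exhaustive threshold search,
# set arithmetic on coordinate pairs, level-sweep flooding.

# distance of every pixel (0-based centers) from a point
oracle_dist <- function(shape, center) {
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2)
}

# union of filled disks by per-pixel scan
oracle_disk_mask <- function(blobs, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(blobs)))
    out <- out | (oracle_dist(shape, c(blobs$row[i], blobs$col[i])) <=
                    blobs$radius_px[i] + 1e-9)
  out
}

# union of donut annuli by per-pixel scan
oracle_donut_mask <- function(blobs, shape, core_fraction = 0.6) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(blobs))) {
    r <- blobs$radius_px[i]
    e <- min(max(round(0.3 * r), 2), 5)
    d <- oracle_dist(shape, c(blobs$row[i], blobs$col[i]))
    out <- out | (d >= core_fraction * r - 1e-9 & d <= r + e + 1e-9)
  }
  out
}

# Euclidean dilation by scanning every pixel against every true pixel
oracle_dilate <- function(mask, radius) {
  tr <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(tr) == 0) return(out)
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      d2 <- (tr[, 1] - i)^2 + (tr[, 2] - j)^2
      if (min(d2) <= radius^2 + 1e-9) out[i, j] <- TRUE
    }
  out
}

# exhaustive Otsu on the 256-bin histogram: every bin boundary is tried and
# scored from per-bin counts and midpoints, one threshold at a time
oracle_otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1), n_bins)
  counts <- tabulate(bin, n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1)) {
    n1 <- sum(counts[1:t]); n2 <- sum(counts) - n1
    if (n1 == 0 || n2 == 0) next
    m1 <- sum(counts[1:t] * mids[1:t]) / n1
    m2 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / n2
    s <- (n1 / sum(counts)) * (n2 / sum(counts)) * (m1 - m2)^2
    if (s > best) { best <- s; best_t <- edges[t + 1] }
  }
  best_t
}

# grayscale erosion/dilation with a disk by direct offset scan
oracle_gray_morph <- function(img, radius, want_min) {
  H <- nrow(img); W <- ncol(img)
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2 + 1e-9, ]
  op <- if (want_min) pmin else pmax
  out <- matrix(if (want_min) Inf else -Inf, H, W)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    src_r <- max(1, 1 - dy):min(H, H - dy)
    src_c <- max(1, 1 - dx):min(W, W - dx)
    shifted <- img[src_r + dy, src_c + dx, drop = FALSE]
    out[src_r, src_c] <- op(out[src_r, src_c], shifted)
  }
  out
}
oracle_opening <- function(img, radius) {
  oracle_gray_morph(oracle_gray_morph(img, radius, TRUE), radius, FALSE)
}

# two-pass Pearson written out longhand
oracle_pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Prominence by level sweep, for images with no tied pixel values: for each
# strict 8-neighbour local maximum, descend through the sorted pixel values
# until the connected component (pixels >= level, BFS) containing the peak
# holds a strictly higher pixel; prominence = peak - that level. The global
# maximum is measured against the image minimum.
oracle_peak_prominence <- function(img) {
  stopifnot(!anyDuplicated(as.numeric(img)))
  H <- nrow(img); W <- ncol(img)
  is_peak <- matrix(TRUE, H, W)
  for (i in 1:H) for (j in 1:W) {
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W || (di == 0 && dj == 0)) next
      if (img[ii, jj] > img[i, j]) is_peak[i, j] <- FALSE
    }
  }
  comp_of <- function(i, j, level) {
    seen <- matrix(FALSE, H, W)
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    hit_higher <- FALSE
    h <- img[i, j]
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W || seen[ii, jj]) next
        if (img[ii, jj] >= level) {
          seen[ii, jj] <- TRUE
          if (img[ii, jj] > h) hit_higher <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
    hit_higher
  }
  levels <- sort(unique(as.numeric(img)), decreasing = TRUE)
  minv <- min(img)
  peaks <- which(is_peak, arr.ind = TRUE)
  res <- list()
  for (k in seq_len(nrow(peaks))) {
    i <- peaks[k, 1]; j <- peaks[k, 2]
    h <- img[i, j]
    prom <- h - minv
    for (level in levels[levels < h]) {
      if (comp_of(i, j, level)) { prom <- h - level; break }
    }
    res[[length(res) + 1]] <- data.frame(row = i - 1, col = j - 1,
                                         height = h, prominence = prom)
  }
  do.call(rbind, res)
}

# greedy nearest-centroid matching of detections to ground truth
match_blobs <- function(detected, truth, max_dist = 2) {
  used <- rep(FALSE, nrow(truth))
  matched <- 0L
  if (nrow(detected) == 0) return(list(matched = 0L, fp = 0L))
  for (i in seq_len(nrow(detected))) {
    d <- sqrt((truth$row - detected$row[i])^2 +
                (truth$col - detected$col[i])^2)
    d[used] <- Inf
    k <- which.min(d)
    if (length(k) && d[k] <= max_dist) { used[k] <- TRUE; matched <- matched + 1L }
  }
  list(matched = matched, fp = nrow(detected) - matched)
}

# small geometry stub for render_* tests without a full scene
make_geom <- function(shape = c(96, 96), cell_r = 40, nuc_r = 12,
                      blobs = data.frame(row = numeric(0), col = numeric(0),
                                         radius_px = numeric(0),
                                         label = character(0))) {
  ctr <- c((shape[1] - 1) / 2, (shape[2] - 1) / 2)
  d <- oracle_dist(shape, ctr)
  list(cell_mask = d <= cell_r, nucleus_mask = d <= nuc_r,
       true_blobs = blobs)
}
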