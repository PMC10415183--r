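# Scale-space LD detection and the masks/filters derived from it.

#' LoG blob-detection configuration
#'
#' Defaults: sigma grid 1.5–8 px over 10 scales covers LD radii of roughly
#' 2–11 px (radius = sqrt(2) * sigma, the extremum relation of the
#' scale-normalized Laplacian of Gaussian for a 2D blob); detections must
#' exceed `log_threshold` times the channel maximum; overlapping detections
#' beyond `overlap_max` (intersection area over the smaller disk) are pruned
#' in favour of the stronger response.
#'
#' @param min_sigma_px,max_sigma_px sigma grid bounds (0 < min < max).
#' @param num_sigma number of (linearly spaced) sigmas, >= 2.
#' @param log_threshold detection threshold relative to the channel maximum.
#' @param overlap_max maximum allowed pairwise disk overlap fraction.
#' @param radius_factor sigma-to-radius conversion factor (default sqrt(2)).
#' @return list of class `detection_config`.
#' @export
detection_config <- function(min_sigma_px = 1.5, max_sigma_px = 8,
                             num_sigma = 10L, log_threshold = 0.05,
                             overlap_max = 0.5, radius_factor = sqrt(2)) {
  if (!(min_sigma_px > 0 && min_sigma_px < max_sigma_px))
    stop("need 0 < min_sigma_px < max_sigma_px")
  if (num_sigma < 2L) stop("num_sigma must be >= 2")
  if (overlap_max < 0 || overlap_max > 1) stop("overlap_max must be in [0,1]")
  if (radius_factor <= 0) stop("radius_factor must be > 0")
  structure(list(min_sigma_px = min_sigma_px, max_sigma_px = max_sigma_px,
                 num_sigma = as.integer(num_sigma),
                 log_threshold = log_threshold,
                 overlap_max = overlap_max, radius_factor = radius_factor),
            class = "detection_config")
}

# Intersection area of two disks over the area of the smaller one.
disk_overlap_fraction <- function(r1, c1, rad1, r2, c2, rad2) {
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  lo <- min(rad1, rad2); hi <- max(rad1, rad2)
  if (d >= rad1 + rad2) return(0)
  if (d <= hi - lo) return(1)
  a1 <- rad1^2 * acos(pmin(pmax((d^2 + rad1^2 - rad2^2) / (2 * d * rad1),
                                -1), 1))
  a2 <- rad2^2 * acos(pmin(pmax((d^2 + rad2^2 - rad1^2) / (2 * d * rad2),
                                -1), 1))
  a3 <- 0.5 * sqrt(pmax((-d + rad1 + rad2) * (d + rad1 - rad2) *
                          (d - rad1 + rad2) * (d + rad1 + rad2), 0))
  (a1 + a2 - a3) / (pi * lo^2)
}

#' Detect lipid droplets as scale-space blobs
#'
#' Builds the scale-normalized Laplacian-of-Gaussian response stack over the
#' configured sigma grid, finds 3D local maxima above threshold, converts
#' sigma to radius, restricts centroids to the cell mask if an ROI is given,
#' and greedily prunes overlapping detections (strongest response first;
#' ties broken by larger radius, then smaller (row, col)).
#'
#' @param channel background-subtracted intensity matrix.
#' @param roi optional [cell_roi()]; detections outside its cell mask are
#'   discarded.
#' @param cfg a [detection_config()].
#' @return object of class `blob_set`: a data.frame with columns `row`,
#'   `col`, `radius_px`, `log_response` plus attributes `detection_config`
#'   and `source_channel`.
#' @export
detect_lds_log <- function(channel, roi = NULL, cfg = detection_config()) {
  stopifnot(is.matrix(channel), inherits(cfg, "detection_config"))
  H <- nrow(channel); W <- ncol(channel)
  empty <- blob_set(data.frame(row = numeric(0), col = numeric(0),
                               radius_px = numeric(0),
                               log_response = numeric(0)), cfg)
  mx <- max(channel)
  if (!is.finite(mx) || mx <= 0) return(empty)
  sigmas <- seq(cfg$min_sigma_px, cfg$max_sigma_px,
                length.out = cfg$num_sigma)
  stack <- array(0, dim = c(H, W, cfg$num_sigma))
  for (s in seq_along(sigmas))
    stack[, , s] <- cpp_norm_log(channel, sigmas[s])
  thr <- cfg$log_threshold * mx
  pk <- cpp_stack_maxima(as.numeric(stack), H, W, length(sigmas), thr)
  if (nrow(pk) == 0L) return(empty)
  # sub-pixel / sub-scale localization: 1D quadratic interpolation of the
  # response through each maximum, offsets clamped to half a grid step
  quad_off <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    off <- ifelse(abs(den) > 1e-300, 0.5 * (fm - fp) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  n <- nrow(pk)
  rows <- pk[, 1L]; cols <- pk[, 2L]; sidx <- pk[, 3L]
  dr <- ds <- dc <- numeric(n)
  for (t in seq_len(n)) {
    i <- rows[t] + 1L; j <- cols[t] + 1L; s <- sidx[t]
    if (i > 1L && i < H)
      dr[t] <- quad_off(stack[i - 1L, j, s], stack[i, j, s],
                        stack[i + 1L, j, s])
    if (j > 1L && j < W)
      dc[t] <- quad_off(stack[i, j - 1L, s], stack[i, j, s],
                        stack[i, j + 1L, s])
    if (s > 1L && s < cfg$num_sigma)
      ds[t] <- quad_off(stack[i, j, s - 1L], stack[i, j, s],
                        stack[i, j, s + 1L])
  }
  dsig <- if (cfg$num_sigma > 1L) sigmas[2L] - sigmas[1L] else 0
  df <- data.frame(row = rows + dr, col = cols + dc,
                   radius_px = cfg$radius_factor * (sigmas[sidx] + ds * dsig),
                   log_response = pk[, 4L])
  if (!is.null(roi)) {
    cm <- if (inherits(roi, "cell_roi")) roi$cell_mask else as_mask_matrix(roi)
    keep <- cm[cbind(round(df$row) + 1L, round(df$col) + 1L)]
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(empty)
  # deterministic order: response desc, radius desc, then (row, col) asc
  ord <- order(-df$log_response, -df$radius_px, df$row, df$col)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i == nrow(df)) break
    for (j in seq(i + 1L, nrow(df))) {
      if (!keep[j]) next
      ov <- disk_overlap_fraction(df$row[i], df$col[i], df$radius_px[i],
                                  df$row[j], df$col[j], df$radius_px[j])
      if (ov > cfg$overlap_max) keep[j] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[!duplicated(df[, c("row", "col")]), , drop = FALSE]
  rownames(df) <- NULL
  blob_set(df, cfg)
}

#' Construct a blob set
#'
#' @param blobs data.frame with columns `row`, `col`, `radius_px` and
#'   optionally `log_response`.
#' @param cfg optional [detection_config()] recorded with the set.
#' @param source_channel channel name the blobs were detected on.
#' @return data.frame of class `blob_set`.
#' @export
blob_set <- function(blobs, cfg = NULL, source_channel = NA_character_) {
  stopifnot(is.data.frame(blobs),
            all(c("row", "col", "radius_px") %in% names(blobs)))
  if (nrow(blobs) && any(blobs$radius_px <= 0))
    stop("blob radii must be positive")
  if (anyDuplicated(blobs[, c("row", "col")]))
    stop("duplicate blob centroids")
  structure(blobs, class = c("blob_set", "data.frame"),
            detection_config = cfg, source_channel = source_channel)
}

#' Filled-disk mask from blobs
#'
#' Union of filled disks (Euclidean distance from centroid <= radius);
#' overlaps are counted once.
#'
#' @param blobs a [blob_set()] or data.frame with `row`, `col`, `radius_px`.
#' @param shape integer (height, width).
#' @return binary mask.
#' @export
blobs_to_mask <- function(blobs, shape) {
  out <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(nrow(blobs)))
    out <- out | disk_mask(shape, c(blobs$row[i], blobs$col[i]),
                           blobs$radius_px[i])
  binary_mask(out)
}

# LD-surface expansion: 2-5 px, proportional to the radius.
donut_expansion_px <- function(radius_px) {
  pmin(pmax(round(0.3 * radius_px), 2), 5)
}

#' Surface "donut" mask around each LD
#'
#' Per blob, the annulus between `core_fraction * r` and `r + e(r)`, where
#' the outward expansion `e(r) = clip(round(0.3 r), 2, 5)` px grows with the
#' droplet. The union over blobs isolates surface-bound decorator signal
#' while excluding the droplet core.
#'
#' @inheritParams blobs_to_mask
#' @param core_fraction inner edge of the annulus as a fraction of the
#'   radius, in (0, 1). Default 0.6.
#' @param expansion function mapping radius to outward expansion in px;
#'   default [donut_expansion_px].
#' @return binary mask.
#' @export
surface_donut_mask <- function(blobs, shape, core_fraction = 0.6,
                               expansion = donut_expansion_px) {
  if (!(core_fraction > 0 && core_fraction < 1))
    stop("core_fraction must be in (0, 1)")
  out <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(nrow(blobs))) {
    r <- blobs$radius_px[i]
    d <- dist_grid(shape, c(blobs$row[i], blobs$col[i]))
    out <- out | (d >= core_fraction * r - 1e-9 &
                    d <= r + expansion(r) + 1e-9)
  }
  binary_mask(out)
}

#' Topographic prominence of every local peak
#'
#' @param channel intensity matrix.
#' @return data.frame with 0-based `row`, `col`, `height`, `prominence`
#'   (the global maximum is measured against the image minimum).
#' @export
peak_prominences <- function(channel) {
  stopifnot(is.matrix(channel))
  pk <- cpp_peak_prominence(channel)
  data.frame(row = pk[, 1L], col = pk[, 2L], height = pk[, 3L],
             prominence = pk[, 4L])
}

#' Count local maxima by topographic prominence
#'
#' Counts intensity peaks whose prominence (height above the highest saddle
#' connecting them to a larger peak; the global maximum is measured against
#' the image minimum) strictly exceeds the threshold — the "Find maxima"
#' style spot count.
#'
#' @param channel intensity matrix.
#' @param roi optional mask or [cell_roi()]; only peaks inside it count.
#' @param prominence positive prominence threshold.
#' @return integer count.
#' @export
count_local_maxima <- function(channel, roi = NULL, prominence) {
  stopifnot(is.matrix(channel), prominence > 0)
  pk <- cpp_peak_prominence(channel)
  if (nrow(pk) == 0L) return(0L)
  keep <- pk[, 4L] > prominence
  if (!is.null(roi)) {
    cm <- if (inherits(roi, "cell_roi")) roi$cell_mask else as_mask_matrix(roi)
    keep <- keep & cm[cbind(pk[, 1L] + 1L, pk[, 2L] + 1L)]
  }
  sum(keep)
}

# Pearson correlation between two channels over a square patch centered at
# (row, col) with the given halfwidth, clipped to the image.
patch_correlation <- function(channel_a, channel_b, row, col, halfwidth) {
  H <- nrow(channel_a); W <- ncol(channel_a)
  r0 <- max(round(row) - halfwidth, 0); r1 <- min(round(row) + halfwidth, H - 1)
  c0 <- max(round(col) - halfwidth, 0); c1 <- min(round(col) + halfwidth, W - 1)
  a <- channel_a[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)]
  b <- channel_b[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Filter true mature LDs by local anticorrelation with a surface marker
#'
#' For tissue fields where a surface decorator (e.g. an mScarlet-tagged
#' LD-coat protein) labels the droplet monolayer: a genuine mature LD has a
#' marker-dark, dye-bright core, so the Pearson correlation between the LD
#' dye and marker channels over a small patch around the detection is
#' negative; non-specific spots light up in both channels and correlate
#' positively. Keeps blobs with patch correlation < 0; degenerate (constant)
#' patches are dropped with a warning.
#'
#' @param blobs a [blob_set()] detected on `ld_channel`.
#' @param ld_channel,marker_channel intensity matrices of identical shape.
#' @param patch_halfwidth function mapping the blob radius to the patch
#'   halfwidth in px; default `max(ceil(1.5 r), 3)`.
#' @return filtered `blob_set` with an added `patch_correlation` column.
#' @export
filter_mature_lds <- function(blobs, ld_channel, marker_channel,
                              patch_halfwidth = function(r)
                                max(ceiling(1.5 * r), 3)) {
  stopifnot(identical(dim(ld_channel), dim(marker_channel)))
  if (nrow(blobs) == 0L) {
    b <- as.data.frame(blobs)
    b$patch_correlation <- numeric(0)
    return(blob_set(b, attr(blobs, "detection_config")))
  }
  cors <- vapply(seq_len(nrow(blobs)), function(i)
    patch_correlation(ld_channel, marker_channel, blobs$row[i],
                      blobs$col[i], patch_halfwidth(blobs$radius_px[i])),
    numeric(1))
  if (anyNA(cors))
    warning(sum(is.na(cors)), " blob(s) dropped: constant patch")
  keep <- !is.na(cors) & cors < 0
  out <- as.data.frame(blobs)[keep, , drop = FALSE]
  out$patch_correlation <- cors[keep]
  rownames(out) <- NULL
  blob_set(out, attr(blobs, "detection_config"),
           attr(blobs, "source_channel"))
}
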