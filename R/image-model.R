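#' Multi-channel image container
#'
#' Bundles named 2D intensity channels that share one pixel grid, together
#' with the physical pixel size. Intensities are kept in the units they were
#' acquired in (no rescaling to \[0, 1\]): every downstream statistic is a
#' ratio or correlation and therefore scale-invariant.
#'
#' @param channels named list of numeric matrices, all the same dimension,
#'   finite and non-negative.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param bit_depth source bit depth, kept as metadata only.
#' @return an object of class `mc_image` with fields `channels`,
#'   `pixel_size_um`, `bit_depth`.
#' @export
mc_image <- function(channels, pixel_size_um = 0.107, bit_depth = 16L) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every channel must be a 2D matrix")
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all channels must share identical dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch)))
      stop("channel '", nm, "' contains non-finite values")
    if (any(ch < 0))
      stop("channel '", nm, "' contains negative intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(list(channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 bit_depth = as.integer(bit_depth)),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<mc_image> %d x %d px, %.4g um/px, channels: %s\n",
              d[1L], d[2L], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mc_image <- function(x) dim(x$channels[[1L]])

#' Extract a channel matrix from an mc_image
#'
#' @param image an [mc_image()].
#' @param name channel name.
#' @return numeric matrix.
#' @export
get_channel <- function(image, name) {
  stopifnot(inherits(image, "mc_image"))
  if (!name %in% names(image$channels))
    stop("no channel named '", name, "'; available: ",
         paste(names(image$channels), collapse = ", "))
  image$channels[[name]]
}

#' Binary pixel mask
#'
#' A logical matrix wrapper used for cell masks, nuclear masks, LD masks,
#' donut masks and peripheral masks. Plain logical matrices are accepted
#' anywhere a mask is expected; this constructor just validates.
#'
#' @param grid logical matrix (NAs not allowed).
#' @return logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(grid) {
  if (is.matrix(grid) && is.numeric(grid)) grid <- grid != 0
  if (!is.matrix(grid) || !is.logical(grid))
    stop("`grid` must be a logical matrix")
  if (anyNA(grid)) stop("mask contains NA")
  class(grid) <- c("binary_mask", class(grid))
  grid
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) {
    m <- unclass(mask)
  } else if (is.matrix(mask) && is.logical(mask)) {
    m <- mask
  } else if (is.matrix(mask) && is.numeric(mask)) {
    m <- mask != 0
  } else stop("expected a logical matrix mask")
  if (anyNA(m)) stop("mask contains NA")
  m
}

#' Mask pixel area
#' @param mask binary mask.
#' @return number of true pixels.
#' @export
mask_area <- function(mask) sum(as_mask_matrix(mask))

#' Cell region of interest
#'
#' A manually or synthetically outlined single cell: a cell mask plus the
#' nucleus mask it contains.
#'
#' @param cell_mask binary mask of the whole cell (non-empty).
#' @param nucleus_mask binary mask of the nucleus; must be a subset of
#'   `cell_mask`.
#' @param cell_id identifier string.
#' @return object of class `cell_roi`.
#' @export
cell_roi <- function(cell_mask, nucleus_mask = NULL, cell_id = "cell") {
  cm <- as_mask_matrix(cell_mask)
  if (!any(cm)) stop("cell mask is empty")
  if (is.null(nucleus_mask)) {
    nm <- matrix(FALSE, nrow(cm), ncol(cm))
  } else {
    nm <- as_mask_matrix(nucleus_mask)
    if (!identical(dim(nm), dim(cm)))
      stop("nucleus mask dimensions differ from cell mask")
    if (any(nm & !cm))
      stop("nucleus mask is not contained in the cell mask")
  }
  structure(list(cell_mask = cm, nucleus_mask = nm,
                 cell_id = as.character(cell_id)),
            class = "cell_roi")
}

# 3x3 mean filter with replicated edges (Fiji-style pre-smoothing of the
# background estimate; keeps the morphological opening from tracking noise
# minima on shot-noise-limited images).
mean3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- c(1L, 1:(H - 1L)); dn <- c(2:H, H)
  lf <- c(1L, 1:(W - 1L)); rt <- c(2:W, W)
  (m[up, lf] + m[up, ] + m[up, rt] +
     m[, lf] + m + m[, rt] +
     m[dn, lf] + m[dn, ] + m[dn, rt]) / 9
}

#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the channel with a flat disk structuring element (the classical
#' rolling-ball approximation used in Fiji-style preprocessing) and subtracts
#' it. Flat regions map to ~0; features smaller than the ball are preserved.
#' By default the background is estimated on a lightly smoothed (3x3 mean)
#' copy, as Fiji does: on noisy images a raw opening tracks local noise
#' minima and under-subtracts the true pedestal.
#'
#' @param channel numeric matrix.
#' @param ball_radius_px disk radius in pixels (>= 1). Default 50.
#' @param presmooth use the Fiji-style estimation pipeline (default TRUE):
#'   3x3 mean smoothing and, for large balls, rolling on a block-mean
#'   shrunk copy (factor 2 for radius > 15, 4 for radius > 31) with
#'   bilinear upscale of the estimate. `FALSE` gives the pure grayscale
#'   opening of the raw input (the exact morphological contract). The
#'   subtraction is always applied to the original pixels.
#' @return background-subtracted matrix, everywhere >= 0 and <= input.
#' @export
subtract_background <- function(channel, ball_radius_px = 50,
                                presmooth = TRUE) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (!is.finite(ball_radius_px) || ball_radius_px < 1)
    stop("`ball_radius_px` must be >= 1")
  if (!presmooth) {
    bg <- cpp_gray_dilate_disk(cpp_gray_erode_disk(channel, ball_radius_px),
                               ball_radius_px)
    return(channel - pmin(bg, channel))
  }
  src <- mean3x3(channel)
  shrink <- if (ball_radius_px > 31) 4L else if (ball_radius_px > 15) 2L
            else 1L
  if (shrink > 1L) {
    small <- block_mean(src, shrink)
    op <- cpp_gray_dilate_disk(
      cpp_gray_erode_disk(small, ball_radius_px / shrink),
      ball_radius_px / shrink)
    bg <- bilinear_upscale(op, shrink, dim(channel))
  } else {
    bg <- cpp_gray_dilate_disk(cpp_gray_erode_disk(src, ball_radius_px),
                               ball_radius_px)
  }
  channel - pmin(bg, channel)   # background never exceeds the pixel itself
}

# block-mean downscale by integer factor s (edge blocks may be partial)
block_mean <- function(m, s) {
  H <- nrow(m); W <- ncol(m)
  h <- ceiling(H / s); w <- ceiling(W / s)
  ri <- rep(seq_len(h), each = s)[seq_len(H)]
  ci <- rep(seq_len(w), each = s)[seq_len(W)]
  sums <- rowsum(m, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri, h), tabulate(ci, w))
  sums / cnt
}

# bilinear upscale of a shrunk background estimate back to full resolution;
# shrunk pixel (i, j) represents full-resolution block center
# ((i - 0.5) * s - 0.5, (j - 0.5) * s - 0.5) in 0-based coordinates
bilinear_upscale <- function(m, s, out_dim) {
  H <- out_dim[1L]; W <- out_dim[2L]
  h <- nrow(m); w <- ncol(m)
  interp_idx <- function(n_out, n_in) {
    x <- ((0:(n_out - 1)) + 0.5) / s - 0.5   # position in shrunk units
    x <- pmin(pmax(x, 0), n_in - 1)
    i0 <- pmin(floor(x), n_in - 2)
    list(i0 = i0 + 1, frac = x - i0)
  }
  ri <- interp_idx(H, h); ci <- interp_idx(W, w)
  m00 <- m[ri$i0, ci$i0, drop = FALSE]
  m10 <- m[ri$i0 + 1, ci$i0, drop = FALSE]
  m01 <- m[ri$i0, ci$i0 + 1, drop = FALSE]
  m11 <- m[ri$i0 + 1, ci$i0 + 1, drop = FALSE]
  fr <- matrix(ri$frac, H, W)
  fc <- matrix(ci$frac, H, W, byrow = TRUE)
  m00 * (1 - fr) * (1 - fc) + m10 * fr * (1 - fc) +
    m01 * (1 - fr) * fc + m11 * fr * fc
}

#' Otsu threshold of a channel
#'
#' Exhaustive search over a 256-bin histogram between the channel minimum and
#' maximum for the threshold maximizing between-class variance. The returned
#' value is the upper edge of the chosen bin, so `channel > threshold` is the
#' foreground.
#'
#' @param channel numeric matrix with at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return threshold value, or `NA` for a constant channel.
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  v <- as.numeric(channel)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || lo == hi) return(NA_real_)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- mids * w
  cw <- cumsum(w)                       # class-0 weight up to bin t
  cmu <- cumsum(mu)
  mu_t <- cmu[n_bins]
  valid <- cw > 0 & cw < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * cw[valid] - cmu[valid])^2 /
    (cw[valid] * (1 - cw[valid]))
  t_idx <- which.max(bcv)
  edges[t_idx + 1L]
}

#' Otsu foreground mask
#'
#' Pixels strictly above the Otsu threshold. A constant channel yields an
#' empty mask with a warning (degenerate cells must flow through batch runs).
#'
#' @inheritParams otsu_threshold
#' @param within optional mask restricting both the histogram and the output.
#' @return binary mask.
#' @export
otsu_mask <- function(channel, within = NULL, n_bins = 256L) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (is.null(within)) {
    thr <- otsu_threshold(channel, n_bins)
    if (is.na(thr)) {
      warning("constant channel: Otsu mask is empty")
      return(binary_mask(matrix(FALSE, nrow(channel), ncol(channel))))
    }
    return(binary_mask(channel > thr))
  }
  w <- as_mask_matrix(within)
  if (!identical(dim(w), dim(channel))) stop("`within` dimension mismatch")
  vals <- channel[w]
  if (length(vals) == 0L || min(vals) == max(vals)) {
    warning("constant channel within ROI: Otsu mask is empty")
    return(binary_mask(matrix(FALSE, nrow(channel), ncol(channel))))
  }
  thr <- otsu_threshold(matrix(vals, ncol = 1L), n_bins)
  binary_mask(channel > thr & w)
}

#' Euclidean mask dilation
#'
#' Exact Euclidean dilation via the squared distance transform: the result
#' contains every pixel within distance `radius_px` of a true input pixel.
#' Unlike iterated 3x3 dilation, this stays circular for large radii (the
#' peripheral mask uses a 160 px dilation).
#'
#' @param mask binary mask.
#' @param radius_px dilation radius in pixels (>= 0).
#' @return binary mask; always a superset of the input.
#' @export
dilate_mask <- function(mask, radius_px) {
  m <- as_mask_matrix(mask)
  if (!is.finite(radius_px) || radius_px < 0)
    stop("`radius_px` must be >= 0")
  if (radius_px == 0 || !any(m)) return(binary_mask(m))
  d2 <- cpp_sq_edt(m)
  binary_mask(d2 <= radius_px * radius_px + 1e-9)
}

#' Mask union and difference
#'
#' Pixelwise OR, and pixelwise `a AND NOT b`.
#'
#' @param a,b binary masks of identical shape.
#' @return binary mask.
#' @export
mask_union <- function(a, b) {
  ma <- as_mask_matrix(a); mb <- as_mask_matrix(b)
  if (!identical(dim(ma), dim(mb))) stop("mask shape mismatch")
  binary_mask(ma | mb)
}

#' @rdname mask_union
#' @export
mask_difference <- function(a, b) {
  ma <- as_mask_matrix(a); mb <- as_mask_matrix(b)
  if (!identical(dim(ma), dim(mb))) stop("mask shape mismatch")
  binary_mask(ma & !mb)
}
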