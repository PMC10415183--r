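# Per-cell statistics: enrichment at LDs, masked Pearson colocalization,
# LD-area morphometry and density normalization.

#' Sum-based decorator enrichment at LDs
#'
#' Enrichment is the ratio of LD-localized decorator (sum of decorator
#' intensity over the filled disks of the detected radii, inside the cell
#' mask) to total decorator (sum over the whole cell mask). Channels should
#' be background-subtracted first.
#'
#' @param decorator_channel intensity matrix.
#' @param blobs [blob_set()] of detected LDs.
#' @param roi [cell_roi()] or cell mask.
#' @return list with `cell_id`, `total_intensity`, `ld_intensity`,
#'   `enrichment_sum` (in \[0, 1\]; `NA` with a warning when the cell holds
#'   no signal).
#' @export
enrichment_sum <- function(decorator_channel, blobs, roi) {
  cm <- roi_cell_mask(roi)
  stopifnot(identical(dim(cm), dim(decorator_channel)))
  total <- sum(decorator_channel[cm])
  ld_mask <- as_mask_matrix(blobs_to_mask(blobs, dim(decorator_channel))) & cm
  ld_sum <- sum(decorator_channel[ld_mask])
  if (total <= 0) {
    warning("zero total intensity in cell mask: enrichment undefined")
    ratio <- NA_real_
  } else ratio <- ld_sum / total
  list(cell_id = roi_cell_id(roi), total_intensity = total,
       ld_intensity = ld_sum, enrichment_sum = ratio)
}

#' Mean-based decorator enrichment in an LD (or donut) mask
#'
#' Ratio of the mean decorator intensity inside the mask (intersected with
#' the cell) to the mean over the entire cell; values above 1 indicate
#' enrichment. Pair with [surface_donut_mask()] to quantify surface-bound
#' decorator.
#'
#' @param decorator_channel intensity matrix.
#' @param ld_mask binary mask (LD or donut).
#' @param roi [cell_roi()] or cell mask.
#' @return list with `cell_id`, `enrichment_mean` (`NA` with a warning for
#'   an empty mask).
#' @export
enrichment_mean <- function(decorator_channel, ld_mask, roi) {
  cm <- roi_cell_mask(roi)
  m <- as_mask_matrix(ld_mask) & cm
  if (!any(m)) {
    warning("empty LD mask within cell: mean enrichment undefined")
    return(list(cell_id = roi_cell_id(roi), enrichment_mean = NA_real_))
  }
  mean_cell <- mean(decorator_channel[cm])
  if (mean_cell == 0) {
    warning("zero mean cell intensity: mean enrichment undefined")
    return(list(cell_id = roi_cell_id(roi), enrichment_mean = NA_real_))
  }
  list(cell_id = roi_cell_id(roi),
       enrichment_mean = mean(decorator_channel[m]) / mean_cell)
}

#' Masked Pearson correlation between two channels
#'
#' Standard two-pass (mean-centered) Pearson correlation over the pixel
#' pairs inside the mask; the single-pass formula is avoided for its
#' catastrophic cancellation on bright images.
#'
#' @param channel_a,channel_b intensity matrices of identical shape.
#' @param mask binary mask with at least 2 true pixels.
#' @param region label recorded in the result (e.g. `"ld_localized"`,
#'   `"peripheral"`).
#' @return list with `pearson_r` (`NA` with a warning if either channel is
#'   constant within the mask), `n_pixels`, `region`.
#' @export
masked_pearson <- function(channel_a, channel_b, mask, region = "mask") {
  stopifnot(identical(dim(channel_a), dim(channel_b)))
  m <- as_mask_matrix(mask)
  stopifnot(identical(dim(m), dim(channel_a)))
  n <- sum(m)
  if (n < 2L) stop("mask must contain at least 2 pixels")
  a <- channel_a[m]; b <- channel_b[m]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant channel within mask: correlation undefined")
    return(list(pearson_r = NA_real_, n_pixels = n, region = region))
  }
  list(pearson_r = stats::cor(a, b), n_pixels = n, region = region)
}

#' Cell-periphery mask
#'
#' The whole-cell mask minus the nucleus dilated by `dilation_px` (default
#' 160 px, the convention for excluding the perinuclear region from
#' LD-lysosome colocalization).
#'
#' @param roi a [cell_roi()].
#' @param dilation_px Euclidean dilation radius for the nucleus.
#' @return binary mask (possibly empty).
#' @export
peripheral_mask <- function(roi, dilation_px = 160) {
  stopifnot(inherits(roi, "cell_roi"))
  mask_difference(roi$cell_mask, dilate_mask(roi$nucleus_mask, dilation_px))
}

#' LD area fraction of the cell by Otsu segmentation
#'
#' Total LD area (Otsu foreground of the LD channel, by default computed
#' within the cell ROI) divided by the cell area.
#'
#' @param ld_channel background-subtracted LD (BODIPY) channel.
#' @param roi [cell_roi()] or cell mask.
#' @param scope `"cell"` (Otsu histogram restricted to the ROI, the default)
#'   or `"image"` (whole-image threshold).
#' @return list with `cell_id`, `ld_area_px`, `cell_area_px`,
#'   `area_fraction`.
#' @export
ld_area_fraction <- function(ld_channel, roi, scope = c("cell", "image")) {
  scope <- match.arg(scope)
  cm <- roi_cell_mask(roi)
  if (!any(cm)) stop("empty cell mask")
  m <- if (scope == "cell") otsu_mask(ld_channel, within = cm)
       else otsu_mask(ld_channel)
  ld_area <- sum(as_mask_matrix(m) & cm)
  list(cell_id = roi_cell_id(roi), ld_area_px = ld_area,
       cell_area_px = sum(cm), area_fraction = ld_area / sum(cm))
}

#' LD density per physical area
#'
#' Count of (true) LDs divided by the physical field area
#' `H * W * pixel_size_um^2`. For the standard tissue quantification field
#' of 2,048 x 2,048 px at 0.066 um/px the normalizing area is 18,270 um^2.
#'
#' @param ld_count number of LDs.
#' @param image_shape integer (height, width) in px.
#' @param pixel_size_um pixel size (> 0).
#' @return density in LDs per um^2.
#' @export
ld_density_per_area <- function(ld_count, image_shape, pixel_size_um) {
  stopifnot(pixel_size_um > 0, length(image_shape) == 2L)
  ld_count / (as.numeric(image_shape[1L]) * as.numeric(image_shape[2L]) *
                pixel_size_um^2)
}

roi_cell_mask <- function(roi) {
  if (inherits(roi, "cell_roi")) roi$cell_mask else as_mask_matrix(roi)
}

roi_cell_id <- function(roi) {
  if (inherits(roi, "cell_roi")) roi$cell_id else NA_character_
}
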