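# Dual-excitation Keima ratiometry: reporter mask, per-pixel 561/488
# ratios, QC flags and normalization to a control condition.

#' Keima reporter mask
#'
#' Otsu foreground of the 488-excitation channel unioned with the Otsu
#' foreground of the 561-excitation channel: the total area expressing the
#' reporter regardless of which excitation it currently favours.
#'
#' @param ex488,ex561 intensity matrices of identical shape.
#' @return binary mask with attribute `qc_empty` (TRUE when both channels
#'   were constant and the mask is empty).
#' @export
keima_reporter_mask <- function(ex488, ex561) {
  stopifnot(identical(dim(ex488), dim(ex561)))
  m1 <- withCallingHandlers(otsu_mask(ex488),
                            warning = function(w) invokeRestart("muffleWarning"))
  m2 <- withCallingHandlers(otsu_mask(ex561),
                            warning = function(w) invokeRestart("muffleWarning"))
  out <- mask_union(m1, m2)
  if (!any(out)) {
    warning("both Keima channels constant: empty reporter mask")
    attr(out, "qc_empty") <- TRUE
  } else attr(out, "qc_empty") <- FALSE
  out
}

#' Ratiometric Keima measurement over a mask
#'
#' Computes the per-pixel 561/488 excitation ratio over the mask, excluding
#' pixels whose 488 intensity is at or below a machine-scale floor `eps`
#' (no pseudocount is added: pseudocounts bias dim cells low). Reports both
#' the mean of per-pixel ratios (`mean_ratio`, the headline value, matching
#' ratio-image construction) and the ratio of sums (`total_ratio`).
#'
#' @param ex488,ex561 intensity matrices of identical shape.
#' @param mask non-empty binary mask.
#' @param eps denominator floor; pixels with `ex488 <= eps` are excluded
#'   and counted.
#' @param cell_id identifier carried into the result.
#' @return list of class `keima_result`: `cell_id`, `mask_area_px`,
#'   `n_excluded_pixels`, `mean_ratio`, `total_ratio`, `qc_flags`
#'   (character vector; `"empty_mask"` / `"all_pixels_excluded"`).
#' @export
keima_ratio <- function(ex488, ex561, mask, eps = 1e-9, cell_id = "cell") {
  stopifnot(identical(dim(ex488), dim(ex561)))
  m <- as_mask_matrix(mask)
  qc <- character(0)
  if (!any(m)) {
    warning("empty Keima mask")
    return(structure(list(cell_id = cell_id, mask_area_px = 0L,
                          n_excluded_pixels = 0L, mean_ratio = NA_real_,
                          total_ratio = NA_real_, qc_flags = "empty_mask"),
                     class = "keima_result"))
  }
  a <- ex488[m]; b <- ex561[m]
  ok <- a > eps
  n_excl <- sum(!ok)
  if (!any(ok)) {
    warning("all masked pixels have zero 488 signal")
    return(structure(list(cell_id = cell_id, mask_area_px = sum(m),
                          n_excluded_pixels = n_excl,
                          mean_ratio = NA_real_, total_ratio = NA_real_,
                          qc_flags = "all_pixels_excluded"),
                     class = "keima_result"))
  }
  structure(list(cell_id = cell_id, mask_area_px = sum(m),
                 n_excluded_pixels = n_excl,
                 mean_ratio = mean(b[ok] / a[ok]),
                 total_ratio = sum(b[ok]) / sum(a[ok]),
                 qc_flags = qc),
            class = "keima_result")
}

#' Flag cells suspected of cleaved cytosolic reporter
#'
#' Cells in which the fluorophore has been cleaved off the LD anchor show a
#' diffuse cytosolic fill: the reporter mask covers an implausibly large
#' fraction of the cell. Such cells are flagged (never silently deleted) so
#' the exclusion is visible in the run log.
#'
#' @param reporter_mask Keima reporter mask.
#' @param roi [cell_roi()] or cell mask.
#' @param max_cell_fraction flag threshold on mask-area / cell-area
#'   (default 0.85).
#' @return logical.
#' @export
keima_qc_cleaved <- function(reporter_mask, roi, max_cell_fraction = 0.85) {
  cm <- roi_cell_mask(roi)
  ca <- sum(cm)
  if (ca == 0) return(FALSE)
  sum(as_mask_matrix(reporter_mask) & cm) / ca > max_cell_fraction
}

#' Normalize Keima ratios to a control condition
#'
#' Divides every cell's `mean_ratio` by the mean `mean_ratio` of the control
#' condition group, so the control group averages 1 by construction.
#'
#' @param results data.frame with columns `condition` and `mean_ratio`.
#' @param control_condition name of the control group.
#' @return the data.frame with an added `normalized_ratio` column.
#' @export
normalize_to_control <- function(results, control_condition) {
  stopifnot(is.data.frame(results),
            all(c("condition", "mean_ratio") %in% names(results)))
  ctrl <- results$mean_ratio[results$condition == control_condition]
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) == 0L) stop("control condition '", control_condition,
                               "' has no defined mean_ratio")
  ctrl_mean <- mean(ctrl)
  if (ctrl_mean == 0) stop("control group mean ratio is zero")
  results$normalized_ratio <- results$mean_ratio / ctrl_mean
  results
}
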