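# Synthetic fluorescence-microscopy scenes with exhaustive ground truth.
# One cell per field: a disk-shaped cell containing a nucleus, LDs placed by
# rejection sampling, a decorator protein channel painted as surface rings
# or filled disks with an exact on-LD intensity budget, a lysosome channel
# partially overlapping the LDs, and a two-compartment dual-excitation Keima
# reporter pair. Noise model: Poisson(signal + background) + Gaussian read
# noise, clipped at zero. Ground truth is recorded before noise.

#' Synthetic scene parameters
#'
#' All geometry is in pixels on the (row, col) 0-based grid with pixel
#' centers at integer coordinates; intensities are arbitrary camera units
#' (treated as photon counts by the Poisson noise stage).
#'
#' @param image_size integer (height, width), default 192 x 192.
#' @param pixel_size_um physical pixel size, default 0.107 (spinning-disk
#'   60x objective class).
#' @param cell_radius_px,nucleus_radius_px cell and nucleus disk radii.
#' @param n_lds number of mature LDs.
#' @param ld_radius_range_px (min, max) LD radius, drawn uniformly.
#' @param min_ld_separation_px minimum pairwise centroid distance.
#' @param decorator_mode `"surface_ring"`, `"filled"` or `"absent"`.
#' @param on_ld_intensity_fraction fraction of the decorator channel's total
#'   intensity painted on LDs (exact before noise).
#' @param ring_inner_fraction inner edge of the painted surface ring as a
#'   fraction of the LD radius. Default 1: the decorator coats the droplet
#'   monolayer at and just outside the radius, which is what makes the
#'   BODIPY core anticorrelate with the decorator in small patches.
#' @param ring_pad_px outer extent of the ring beyond the radius (default 2).
#' @param lysosome_overlap_fraction fraction of LDs co-painted in the
#'   lysosome channel.
#' @param keima_lyso_ratio,keima_cyto_ratio true per-pixel 561/488 excitation
#'   ratios of the lysosomal and cytosolic reporter compartments.
#' @param lyso_pixel_fraction fraction of reporter-mask pixels that are
#'   lysosomal.
#' @param noise_gaussian_sd camera read-noise s.d. (default 2).
#' @param noise_poisson logical, apply Poisson shot noise (default TRUE).
#' @param background_level smooth background added to every channel
#'   (default 20).
#' @param ld_peak_intensity LD (BODIPY) disk amplitude above background.
#'   Default 200: with the default background and read noise this is a
#'   signal-to-noise ratio of about 40 (see [snr_to_peak()]).
#' @param decorator_total_intensity total decorator intensity budget.
#' @param psf_sigma_px Gaussian point-spread sigma applied to the LD and
#'   lysosome channels (default 1 px) so blobs have realistic soft edges.
#' @param keima_ex488_intensity reporter brightness in the 488-excitation
#'   channel.
#' @param lyso_punctum_radius_range_px radius range of lysosomal puncta.
#' @param n_nonspecific_spots number of non-specific spots painted filled in
#'   both the LD and decorator channels (tissue-field false positives).
#' @param seed integer seed fixing the whole scene.
#' @return validated list of class `scene_params`.
#' @export
scene_params <- function(image_size = c(192L, 192L),
                         pixel_size_um = 0.107,
                         cell_radius_px = 80,
                         nucleus_radius_px = 28,
                         n_lds = 12L,
                         ld_radius_range_px = c(3, 8),
                         min_ld_separation_px = 20,
                         decorator_mode = "surface_ring",
                         on_ld_intensity_fraction = 0.4,
                         ring_inner_fraction = 1.0,
                         ring_pad_px = 2,
                         lysosome_overlap_fraction = 0.5,
                         keima_lyso_ratio = 3.0,
                         keima_cyto_ratio = 0.5,
                         lyso_pixel_fraction = 0.3,
                         noise_gaussian_sd = 2,
                         noise_poisson = TRUE,
                         background_level = 20,
                         ld_peak_intensity = 200,
                         decorator_total_intensity = 1e6,
                         psf_sigma_px = 1,
                         keima_ex488_intensity = 100,
                         lyso_punctum_radius_range_px = c(3, 6),
                         n_nonspecific_spots = 0L,
                         seed = 1L) {
  p <- as.list(environment())
  stopifnot(length(p$image_size) == 2L, all(p$image_size >= 32),
            p$pixel_size_um > 0,
            p$cell_radius_px > p$nucleus_radius_px,
            p$nucleus_radius_px >= 0,
            p$n_lds >= 0,
            length(p$ld_radius_range_px) == 2L,
            p$ld_radius_range_px[1L] > 0,
            diff(p$ld_radius_range_px) >= 0,
            p$min_ld_separation_px >= 0)
  for (f in c("on_ld_intensity_fraction", "lysosome_overlap_fraction",
              "lyso_pixel_fraction")) {
    v <- p[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be in [0, 1]")
  }
  if (!p$decorator_mode %in% c("surface_ring", "filled", "absent"))
    stop("decorator_mode must be surface_ring, filled or absent")
  if (p$ring_inner_fraction <= 0 || p$ring_inner_fraction > 1)
    stop("ring_inner_fraction must be in (0, 1]")
  stopifnot(p$keima_lyso_ratio > 0, p$keima_cyto_ratio > 0,
            p$noise_gaussian_sd >= 0, p$background_level >= 0,
            p$ld_peak_intensity > 0, p$decorator_total_intensity > 0,
            p$psf_sigma_px >= 0, p$keima_ex488_intensity > 0)
  p$seed <- as.integer(seed)
  structure(p, class = "scene_params")
}

#' Peak intensity giving a target signal-to-noise ratio
#'
#' SNR is defined as peak signal over the noise s.d. at background:
#' `peak / sqrt(background + gaussian_sd^2)` under the Poisson + Gaussian
#' camera model.
#'
#' @param snr target SNR.
#' @param background_level,noise_gaussian_sd noise model parameters.
#' @return peak amplitude in camera units.
#' @export
snr_to_peak <- function(snr, background_level = 20, noise_gaussian_sd = 2) {
  snr * sqrt(background_level + noise_gaussian_sd^2)
}

# Distance-from-point grid (0-based pixel centers at integers).
dist_grid <- function(shape, center) {
  H <- shape[1L]; W <- shape[2L]
  dr <- (0:(H - 1L)) - center[1L]
  dc <- (0:(W - 1L)) - center[2L]
  sqrt(outer(dr^2, dc^2, `+`))
}

disk_mask <- function(shape, center, radius) {
  dist_grid(shape, center) <= radius + 1e-9
}

# Soft-edged disk: per-pixel coverage ramp of width 1 px at the rim.
soft_disk <- function(shape, center, radius) {
  d <- dist_grid(shape, center)
  pmin(pmax(radius + 0.5 - d, 0), 1)
}

place_blobs <- function(shape, cell_center, cell_r, nuc_r, n, radii,
                        min_sep, existing = NULL, max_attempts = 400L) {
  if (!is.null(existing) && nrow(existing)) {
    rows <- existing$row; cols <- existing$col; rads <- existing$radius_px
  } else {
    rows <- numeric(0); cols <- numeric(0); rads <- numeric(0)
  }
  new_r <- numeric(0); new_c <- numeric(0)
  for (k in seq_len(n)) {
    r <- radii[k]
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      # uniform in the annulus of feasible centers
      rho <- sqrt(runif(1, (nuc_r + r + 1)^2, (cell_r - r - 1)^2))
      th <- runif(1, 0, 2 * pi)
      cr <- cell_center[1L] + rho * sin(th)
      cc <- cell_center[2L] + rho * cos(th)
      if (cr < r + 1 || cr > shape[1L] - r - 2 ||
          cc < r + 1 || cc > shape[2L] - r - 2) next
      if (length(rows)) {
        dd <- sqrt((rows - cr)^2 + (cols - cc)^2)
        req <- pmax(min_sep, rads + r + 2)
        if (any(dd < req)) next
      }
      rows <- c(rows, cr); cols <- c(cols, cc); rads <- c(rads, r)
      new_r <- c(new_r, cr); new_c <- c(new_c, cc)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible LD packing: could not place blob ", k, " of ", n,
           " (separation ", min_sep, " px in cell radius ", cell_r, ")")
  }
  data.frame(row = new_r, col = new_c, radius_px = radii[seq_len(n)])
}

#' Render a decorator-protein channel over a scene's geometry
#'
#' Paints the requested fraction of a fixed total intensity on the LDs
#' (surface ring or filled disk) and distributes the remainder uniformly
#' over the cytoplasm (cell minus nucleus minus LD disks). The painted
#' budget is exact before noise: `sum(on-LD pixels) / sum(channel)` equals
#' `on_fraction` to machine precision. Non-specific spots, if present in the
#' geometry, are painted filled at the mature on-LD pixel density and
#' budgeted as off-LD signal.
#'
#' @param geom scene geometry as produced by [simulate_cell()] (a
#'   `synthetic_scene`), or a list with fields `shape`, `cell_mask`,
#'   `nucleus_mask` and `true_blobs`.
#' @param mode `"surface_ring"`, `"filled"` or `"absent"`.
#' @param on_fraction on-LD intensity fraction in \[0, 1\].
#' @param total total channel intensity budget.
#' @param ring_inner_fraction,ring_pad_px surface-ring geometry (see
#'   [scene_params()]).
#' @return numeric matrix with attributes `on_ld_sum` and `off_ld_sum`.
#' @export
render_decorator <- function(geom, mode = "surface_ring", on_fraction = 0.4,
                             total = 1e6, ring_inner_fraction = 1.0,
                             ring_pad_px = 2) {
  if (!mode %in% c("surface_ring", "filled", "absent"))
    stop("invalid decorator mode: ", mode)
  if (on_fraction < 0 || on_fraction > 1)
    stop("on_fraction must be in [0, 1]")
  shape <- dim(geom$cell_mask)
  blobs <- geom$true_blobs
  mature <- blobs[blobs$label == "mature", , drop = FALSE]
  nonspec <- blobs[blobs$label == "nonspecific", , drop = FALSE]
  on_region <- matrix(FALSE, shape[1L], shape[2L])
  ld_disks <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(nrow(blobs)))
    ld_disks <- ld_disks | disk_mask(shape, c(blobs$row[i], blobs$col[i]),
                                     blobs$radius_px[i])
  if (mode != "absent") {
    for (i in seq_len(nrow(mature))) {
      ctr <- c(mature$row[i], mature$col[i]); r <- mature$radius_px[i]
      d <- dist_grid(shape, ctr)
      reg <- if (mode == "surface_ring")
        d >= ring_inner_fraction * r & d <= r + ring_pad_px
      else d <= r + 1e-9
      on_region <- on_region | reg
    }
  }
  cyto <- geom$cell_mask & !geom$nucleus_mask & !ld_disks & !on_region
  ch <- matrix(0, shape[1L], shape[2L])
  n_on <- sum(on_region)
  on_total <- if (mode == "absent") 0 else on_fraction * total
  off_total <- total - on_total
  on_density <- if (n_on > 0) on_total / n_on else 0
  if (n_on > 0) ch[on_region] <- on_density
  # non-specific spots: filled at the on-LD density, out of the off budget
  ns_region <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(nrow(nonspec)))
    ns_region <- ns_region | disk_mask(shape, c(nonspec$row[i],
                                                nonspec$col[i]),
                                       nonspec$radius_px[i])
  ns_region <- ns_region & !on_region
  dens_ns <- if (on_density > 0) on_density else
    off_total / max(sum(cyto) + sum(ns_region), 1)
  ns_total <- min(sum(ns_region) * dens_ns, off_total)
  if (sum(ns_region) > 0) ch[ns_region] <- ns_total / sum(ns_region)
  cyto_total <- off_total - ns_total
  if (sum(cyto) > 0 && cyto_total > 0) ch[cyto] <- cyto_total / sum(cyto)
  attr(ch, "on_ld_sum") <- on_total
  attr(ch, "off_ld_sum") <- ns_total + if (sum(cyto) > 0) cyto_total else 0
  ch
}

#' Render the dual-excitation Keima reporter channel pair
#'
#' The reporter occupies the cytoplasm (cell minus nucleus); a fraction of
#' its pixels, drawn as small lysosomal puncta, carries the acidic
#' (lysosome-favoured) 561/488 per-pixel ratio, the rest the neutral
#' cytosolic ratio. The recorded ground-truth mean ratio is the area-weighted
#' mean of the per-pixel ratio over the realized reporter mask.
#'
#' @param geom scene geometry (see [render_decorator()]).
#' @param lyso_ratio,cyto_ratio true per-pixel 561/488 ratios (> 0).
#' @param lyso_fraction target lysosomal pixel fraction in \[0, 1\].
#' @param ex488_intensity reporter brightness under 488 excitation.
#' @param punctum_radius_range radius range of lysosomal puncta in px.
#' @return list with `ex488`, `ex561` matrices, `reporter_mask`,
#'   `lyso_mask`, and `true_mean_ratio`.
#' @export
render_keima <- function(geom, lyso_ratio = 3.0, cyto_ratio = 0.5,
                         lyso_fraction = 0.3, ex488_intensity = 100,
                         punctum_radius_range = c(3, 6)) {
  stopifnot(lyso_ratio > 0, cyto_ratio > 0,
            lyso_fraction >= 0, lyso_fraction <= 1)
  shape <- dim(geom$cell_mask)
  support <- geom$cell_mask & !geom$nucleus_mask
  n_support <- sum(support)
  lyso <- matrix(FALSE, shape[1L], shape[2L])
  if (lyso_fraction >= 1) {
    lyso <- support
  } else if (lyso_fraction > 0) {
    target <- round(lyso_fraction * n_support)
    sup_idx <- which(support, arr.ind = TRUE)
    guard <- 0L
    while (sum(lyso) < target && guard < 10000L) {
      guard <- guard + 1L
      k <- sample.int(nrow(sup_idx), 1L)
      ctr <- c(sup_idx[k, 1L] - 1L, sup_idx[k, 2L] - 1L)
      r <- runif(1, punctum_radius_range[1L], punctum_radius_range[2L])
      lyso <- lyso | (disk_mask(shape, ctr, r) & support)
    }
  }
  cyto <- support & !lyso
  ex488 <- matrix(0, shape[1L], shape[2L])
  ex488[support] <- ex488_intensity
  ex561 <- matrix(0, shape[1L], shape[2L])
  ex561[lyso] <- ex488_intensity * lyso_ratio
  ex561[cyto] <- ex488_intensity * cyto_ratio
  n_l <- sum(lyso)
  true_mean <- if (n_support > 0)
    (n_l * lyso_ratio + (n_support - n_l) * cyto_ratio) / n_support
  else NA_real_
  list(ex488 = ex488, ex561 = ex561, reporter_mask = binary_mask(support),
       lyso_mask = binary_mask(lyso), true_mean_ratio = true_mean)
}

apply_camera_noise <- function(ch, background, poisson, gaussian_sd) {
  x <- ch + background
  if (poisson) x <- matrix(rpois(length(x), lambda = pmax(x, 0)),
                           nrow(x), ncol(x))
  if (gaussian_sd > 0) x <- x + rnorm(length(x), sd = gaussian_sd)
  pmax(x, 0)
}

#' Simulate a single-cell multi-channel scene
#'
#' Renders channels `ld` (BODIPY-like), `decorator`, `lamp1` (lysosome),
#' `keima488` and `keima561` for one disk-shaped cell, and records the full
#' ground truth before noise: true blob table (with mature / nonspecific
#' labels), per-channel on-LD vs off-LD intensity budgets, the realized
#' Keima compartment ratio, and the noiseless channels. The seed fixes the
#' scene; geometry, intensity and noise use separate derived RNG streams, so
#' toggling noise does not move any blob.
#'
#' @param params a [scene_params()] object.
#' @return object of class `synthetic_scene` with fields `image`
#'   ([mc_image()]), `roi` ([cell_roi()]), `true_blobs` (data.frame `row`,
#'   `col`, `radius_px`, `label`), `intensity_budget`, `true_mean_keima_ratio`,
#'   `keima`, `noiseless` (named list of pre-noise channels), `cell_mask`,
#'   `nucleus_mask`, `params`.
#' @export
simulate_cell <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  shape <- as.integer(p$image_size)
  set.seed(p$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 3L)
  ctr <- c((shape[1L] - 1) / 2, (shape[2L] - 1) / 2)
  cell_mask <- disk_mask(shape, ctr, p$cell_radius_px)
  nucleus_mask <- disk_mask(shape, ctr, p$nucleus_radius_px)

  ## --- geometry stream -----------------------------------------------
  set.seed(streams[1L])
  radii <- runif(p$n_lds, p$ld_radius_range_px[1L], p$ld_radius_range_px[2L])
  blobs <- place_blobs(shape, ctr, p$cell_radius_px, p$nucleus_radius_px,
                       p$n_lds, radii, p$min_ld_separation_px)
  blobs$label <- rep("mature", nrow(blobs))
  if (p$n_nonspecific_spots > 0) {
    ns_radii <- runif(p$n_nonspecific_spots, p$ld_radius_range_px[1L],
                      p$ld_radius_range_px[2L])
    ns <- place_blobs(shape, ctr, p$cell_radius_px, p$nucleus_radius_px,
                      p$n_nonspecific_spots, ns_radii, p$min_ld_separation_px,
                      existing = blobs)
    ns$label <- rep("nonspecific", nrow(ns))
    blobs <- rbind(blobs, ns)
  }
  geom <- list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
               true_blobs = blobs)

  # lysosome channel geometry: subset of LDs + free puncta
  n_m <- sum(blobs$label == "mature")
  n_overlap <- round(p$lysosome_overlap_fraction * n_m)
  overlap_idx <- if (n_m > 0 && n_overlap > 0)
    sample(which(blobs$label == "mature"), n_overlap) else integer(0)
  n_free <- max(1L, round(n_m / 2))
  free_puncta <- if (n_m > 0)
    place_blobs(shape, ctr, p$cell_radius_px, p$nucleus_radius_px, n_free,
                runif(n_free, 2, 4), 6, existing = blobs)
  else data.frame(row = numeric(0), col = numeric(0), radius_px = numeric(0))

  ## --- intensity stream (keima puncta placement lives here) ----------
  set.seed(streams[2L])
  keima <- render_keima(geom, lyso_ratio = p$keima_lyso_ratio,
                        cyto_ratio = p$keima_cyto_ratio,
                        lyso_fraction = p$lyso_pixel_fraction,
                        ex488_intensity = p$keima_ex488_intensity,
                        punctum_radius_range = p$lyso_punctum_radius_range_px)

  ld_ch <- matrix(0, shape[1L], shape[2L])
  for (i in seq_len(nrow(blobs)))
    ld_ch <- pmax(ld_ch, p$ld_peak_intensity *
                    soft_disk(shape, c(blobs$row[i], blobs$col[i]),
                              blobs$radius_px[i]))
  if (p$psf_sigma_px > 0) ld_ch <- cpp_gaussian_blur(ld_ch, p$psf_sigma_px)

  dec_ch <- render_decorator(geom, mode = p$decorator_mode,
                             on_fraction = p$on_ld_intensity_fraction,
                             total = p$decorator_total_intensity,
                             ring_inner_fraction = p$ring_inner_fraction,
                             ring_pad_px = p$ring_pad_px)
  budget <- list(decorator = list(on_ld = attr(dec_ch, "on_ld_sum"),
                                  off_ld = attr(dec_ch, "off_ld_sum")))

  lyso_ch <- matrix(0, shape[1L], shape[2L])
  for (i in overlap_idx)
    lyso_ch <- pmax(lyso_ch, 150 * soft_disk(shape, c(blobs$row[i],
                                                      blobs$col[i]),
                                             blobs$radius_px[i] + 1))
  for (i in seq_len(nrow(free_puncta)))
    lyso_ch <- pmax(lyso_ch, 150 * soft_disk(shape, c(free_puncta$row[i],
                                                      free_puncta$col[i]),
                                             free_puncta$radius_px[i]))
  if (p$psf_sigma_px > 0) lyso_ch <- cpp_gaussian_blur(lyso_ch, p$psf_sigma_px)

  noiseless <- list(ld = ld_ch, decorator = unclass_attr(dec_ch),
                    lamp1 = lyso_ch,
                    keima488 = keima$ex488, keima561 = keima$ex561)

  ## --- noise stream ---------------------------------------------------
  set.seed(streams[3L])
  channels <- lapply(noiseless, apply_camera_noise,
                     background = p$background_level,
                     poisson = p$noise_poisson,
                     gaussian_sd = p$noise_gaussian_sd)

  structure(list(
    image = mc_image(channels, pixel_size_um = p$pixel_size_um),
    roi = cell_roi(cell_mask, nucleus_mask, cell_id = sprintf("sim%06d",
                                                              p$seed)),
    true_blobs = blobs,
    intensity_budget = budget,
    true_mean_keima_ratio = keima$true_mean_ratio,
    keima = keima,
    noiseless = noiseless,
    cell_mask = cell_mask,
    nucleus_mask = nucleus_mask,
    params = p
  ), class = "synthetic_scene")
}

unclass_attr <- function(x) {
  attributes(x) <- attributes(x)["dim"]
  x
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px, %d blob(s) [%d mature], seed %d\n",
    nrow(x$cell_mask), ncol(x$cell_mask), nrow(x$true_blobs),
    sum(x$true_blobs$label == "mature"), x$params$seed))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Emits a multi-page TIFF (channel order as in the image), cell and nucleus
#' mask TIFFs, a ground-truth blob CSV, an intensity-budget CSV, a Keima
#' ground-truth CSV and the resolved parameters as JSON.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem, default the scene's cell id.
#' @return named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, stem = scene$roi$cell_id) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(stem, ".tif")),
    cell_mask = file.path(dir, paste0(stem, "_cell.tif")),
    nucleus_mask = file.path(dir, paste0(stem, "_nucleus.tif")),
    blobs = file.path(dir, paste0(stem, "_blobs.csv")),
    budget = file.path(dir, paste0(stem, "_budget.csv")),
    keima_truth = file.path(dir, paste0(stem, "_keima_truth.csv")),
    params = file.path(dir, paste0(stem, "_params.json")))
  write_image(scene$image, paths[["image"]])
  write_mask(scene$cell_mask, paths[["cell_mask"]])
  write_mask(scene$nucleus_mask, paths[["nucleus_mask"]])
  blobs <- cbind(scene_id = stem, scene$true_blobs)
  utils::write.csv(blobs, paths[["blobs"]], row.names = FALSE)
  bud <- data.frame(channel = "decorator",
                    on_ld = scene$intensity_budget$decorator$on_ld,
                    off_ld = scene$intensity_budget$decorator$off_ld)
  utils::write.csv(bud, paths[["budget"]], row.names = FALSE)
  kt <- data.frame(scene_id = stem,
                   true_mean_ratio = scene$true_mean_keima_ratio,
                   lyso_pixels = mask_area(scene$keima$lyso_mask),
                   reporter_pixels = mask_area(scene$keima$reporter_mask))
  utils::write.csv(kt, paths[["keima_truth"]], row.names = FALSE)
  jsonlite::write_json(unclass(scene$params), paths[["params"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
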