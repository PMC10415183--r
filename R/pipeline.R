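# Batch orchestration: config validation, per-image stage execution,
# per-condition summaries, logging, reproducible outputs.

# FNV-1a 32-bit hash of a string, as 8 hex digits; used to stamp every
# output row with the config that produced it.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

default_run_params <- function() {
  list(background_radius_px = 50,
       detection = detection_config(),
       dilation_px = 160,
       core_fraction = 0.6,
       otsu_scope = "cell",
       keima_eps = 1e-9,
       prominence = NULL,
       coloc_pairs = list(c("lamp1", "ld")),
       control_condition = NULL)
}

#' Load and validate a run configuration
#'
#' The config is JSON with fields `manifest` (path to a CSV with columns
#' `image_path`, `cell_roi_path`, `nucleus_roi_path`, `condition`,
#' `pixel_size_um`), `channel_names` (TIFF page order), `channels` (role to
#' channel-name map with roles among `ld`, `decorator`, `lamp1`, `keima488`,
#' `keima561`), optional `stages` (logical toggles `detect`, `enrich`,
#' `coloc`, `keima`, `morpho`), optional `params` overriding
#' [default_run_params()], `out_dir`, and `seed`. Every referenced path must
#' exist at validation time; validation failures abort before any image is
#' processed.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @return validated config list of class `run_config`, with the manifest
#'   loaded and a `config_hash` attached.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  if (is.null(cfg$manifest)) stop("config must name a manifest")
  base_dir <- if (is.character(config)) dirname(config) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  if (is.character(cfg$manifest)) {
    mpath <- resolve(cfg$manifest)
    if (!file.exists(mpath)) stop("manifest not found: ", cfg$manifest)
    man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  } else man <- as.data.frame(cfg$manifest)
  need <- c("image_path", "condition", "pixel_size_um")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  for (col in intersect(c("image_path", "cell_roi_path", "nucleus_roi_path"),
                        names(man))) {
    paths <- man[[col]]
    paths <- paths[!is.na(paths) & nzchar(paths)]
    for (p in paths) {
      rp <- resolve(p)
      if (!file.exists(rp)) stop("manifest references missing file: ", p)
    }
    man[[col]] <- vapply(man[[col]], function(p)
      if (is.na(p) || !nzchar(p)) p else resolve(p), character(1))
  }
  if (any(man$pixel_size_um <= 0)) stop("pixel_size_um must be > 0")
  if (is.null(cfg$channel_names)) stop("config must give channel_names")
  channels <- cfg$channels
  if (is.null(channels)) channels <- as.list(stats::setNames(
    cfg$channel_names, cfg$channel_names))
  bad <- setdiff(unlist(channels), cfg$channel_names)
  if (length(bad)) stop("channel map names unknown channels: ",
                        paste(bad, collapse = ", "))
  stages <- list(detect = TRUE, enrich = TRUE, coloc = TRUE,
                 keima = TRUE, morpho = TRUE)
  for (s in names(cfg$stages)) stages[[s]] <- isTRUE(cfg$stages[[s]])
  params <- default_run_params()
  for (nm in names(cfg$params)) {
    if (nm == "detection") {
      dc <- cfg$params$detection
      params$detection <- do.call(detection_config, as.list(dc))
    } else params[[nm]] <- cfg$params[[nm]]
  }
  out <- list(manifest = man, channel_names = cfg$channel_names,
              channels = channels, stages = stages, params = params,
              out_dir = if (is.null(cfg$out_dir)) "lipoquant_out"
                        else cfg$out_dir,
              seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
  canon <- jsonlite::toJSON(out[c("channel_names", "channels", "stages",
                                  "params", "seed")],
                            auto_unbox = TRUE, digits = NA, force = TRUE)
  out$config_hash <- fnv1a_hash(as.character(canon))
  class(out) <- "run_config"
  out
}

process_one_image <- function(row, cfg, cell_counter) {
  ch_map <- cfg$channels
  img <- read_image(row$image_path, cfg$channel_names,
                    pixel_size_um = row$pixel_size_um)
  shape <- dim(img)
  cell_id <- sprintf("cell%04d", cell_counter)
  if (!is.null(row$cell_roi_path) && !is.na(row$cell_roi_path) &&
      nzchar(row$cell_roi_path)) {
    cm <- read_mask(row$cell_roi_path)
    nm <- if (!is.null(row$nucleus_roi_path) && !is.na(row$nucleus_roi_path)
              && nzchar(row$nucleus_roi_path))
      read_mask(row$nucleus_roi_path) else NULL
    roi <- cell_roi(cm, nm, cell_id = cell_id)
  } else {
    roi <- cell_roi(matrix(TRUE, shape[1L], shape[2L]), cell_id = cell_id)
  }
  pr <- cfg$params
  getch <- function(role) {
    nm <- ch_map[[role]]
    if (is.null(nm)) NULL else
      subtract_background(get_channel(img, nm), pr$background_radius_px)
  }
  ld_ch <- getch("ld")
  metrics <- list(cell_id = cell_id, condition = row$condition,
                  image_path = row$image_path)
  blobs <- NULL
  if (cfg$stages$detect && !is.null(ld_ch)) {
    blobs <- detect_lds_log(ld_ch, roi, pr$detection)
    metrics$ld_count <- nrow(blobs)
    metrics$density_per_um2 <- ld_density_per_area(
      nrow(blobs), shape, row$pixel_size_um)
  }
  dec_ch <- getch("decorator")
  if (cfg$stages$enrich && !is.null(dec_ch) && !is.null(blobs)) {
    es <- enrichment_sum(dec_ch, blobs, roi)
    metrics$enrichment_sum <- es$enrichment_sum
    donut <- surface_donut_mask(blobs, shape, pr$core_fraction)
    em <- enrichment_mean(dec_ch, donut, roi)
    metrics$enrichment_mean <- em$enrichment_mean
  }
  if (cfg$stages$coloc && length(pr$coloc_pairs)) {
    per_mask <- peripheral_mask(roi, pr$dilation_px)
    for (pair in pr$coloc_pairs) {
      ca <- getch(pair[[1L]]); cb <- getch(pair[[2L]])
      if (is.null(ca) || is.null(cb)) next
      key <- paste0("pearson_peripheral_", pair[[1L]], "_", pair[[2L]])
      if (mask_area(per_mask) >= 2) {
        res <- masked_pearson(ca, cb, per_mask, region = "peripheral")
        metrics[[key]] <- res$pearson_r
      } else metrics[[key]] <- NA_real_
    }
  }
  if (cfg$stages$morpho && !is.null(ld_ch)) {
    mo <- ld_area_fraction(ld_ch, roi, scope = pr$otsu_scope)
    metrics$ld_area_px <- mo$ld_area_px
    metrics$cell_area_px <- mo$cell_area_px
    metrics$area_fraction <- mo$area_fraction
  }
  keima_row <- NULL
  if (cfg$stages$keima && !is.null(ch_map$keima488) &&
      !is.null(ch_map$keima561)) {
    e488 <- getch("keima488")
    e561 <- getch("keima561")
    kmask <- keima_reporter_mask(e488, e561)
    kr <- keima_ratio(e488, e561, kmask, eps = pr$keima_eps,
                      cell_id = cell_id)
    cleaved <- keima_qc_cleaved(kmask, roi)
    keima_row <- data.frame(
      cell_id = cell_id, condition = row$condition,
      mask_area_px = kr$mask_area_px,
      n_excluded_pixels = kr$n_excluded_pixels,
      mean_ratio = kr$mean_ratio, total_ratio = kr$total_ratio,
      qc_flags = paste(c(kr$qc_flags,
                         if (cleaved) "cleaved_reporter_suspected"),
                       collapse = ";"),
      stringsAsFactors = FALSE)
  }
  blob_rows <- if (!is.null(blobs) && nrow(blobs)) {
    data.frame(image_id = basename(row$image_path), cell_id = cell_id,
               as.data.frame(blobs)[, c("row", "col", "radius_px",
                                        "log_response")],
               stringsAsFactors = FALSE)
  } else NULL
  list(metrics = as.data.frame(metrics, stringsAsFactors = FALSE),
       keima = keima_row, blobs = blob_rows)
}

#' Run the full quantification pipeline over a manifest
#'
#' Executes the enabled stages per image, writes `per_cell_metrics.csv`,
#' `keima_metrics.csv`, `blobs.csv`, `condition_summary.csv`, a run log and
#' the resolved config into the output directory, and returns the tables.
#' Per-image failures are logged and skipped; the returned `n_failed`
#' reflects them. Identical config and inputs give identical outputs.
#'
#' @param config path to a JSON run config or a config list
#'   (see [load_run_config()]).
#' @param out_dir optional override of the config's output directory.
#' @return list with `per_cell`, `keima`, `blobs`, `summary` data.frames
#'   and `n_failed`, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log_lines <- character(0)
  logit <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
  }
  per_cell <- list(); keima <- list(); blobs <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(cfg$manifest))) {
    row <- as.list(cfg$manifest[i, ])
    res <- tryCatch(process_one_image(row, cfg, i), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      logit("ERROR image %s: %s", row$image_path, conditionMessage(res))
      next
    }
    logit("OK image %s (%s): %d blob(s)", row$image_path, row$condition,
          if (is.null(res$blobs)) 0L else nrow(res$blobs))
    if (!is.null(res$keima) && grepl("cleaved", res$keima$qc_flags))
      logit("QC image %s: cleaved reporter suspected (flagged, not removed)",
            row$image_path)
    per_cell[[length(per_cell) + 1L]] <- res$metrics
    if (!is.null(res$keima)) keima[[length(keima) + 1L]] <- res$keima
    if (!is.null(res$blobs)) blobs[[length(blobs) + 1L]] <- res$blobs
  }
  bind <- function(lst) if (length(lst)) do.call(rbind_fill, list(lst))
    else data.frame()
  per_cell_df <- bind(per_cell)
  keima_df <- bind(keima)
  blobs_df <- bind(blobs)
  if (nrow(keima_df) && !is.null(cfg$params$control_condition))
    keima_df <- normalize_to_control(keima_df,
                                     cfg$params$control_condition)
  if (nrow(per_cell_df)) per_cell_df$config_hash <- cfg$config_hash
  if (nrow(keima_df)) keima_df$config_hash <- cfg$config_hash
  metric_cols <- setdiff(names(per_cell_df),
                         c("cell_id", "condition", "image_path",
                           "config_hash"))
  summary_df <- summarize_condition(per_cell_df, metric_cols)
  wr <- function(df, name) utils::write.csv(
    df, file.path(cfg$out_dir, name), row.names = FALSE)
  wr(per_cell_df, "per_cell_metrics.csv")
  wr(keima_df, "keima_metrics.csv")
  wr(blobs_df, "blobs.csv")
  wr(summary_df, "condition_summary.csv")
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  jsonlite::write_json(
    cfg[c("channel_names", "channels", "stages", "params", "seed",
          "config_hash")],
    file.path(cfg$out_dir, "resolved_config.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(per_cell = per_cell_df, keima = keima_df,
                 blobs = blobs_df, summary = summary_df,
                 n_failed = n_failed))
}

# rbind data.frames with possibly different columns (missing -> NA).
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

#' Per-condition summary (mean +/- s.d.)
#'
#' Aggregates per-cell metric columns by condition: n, mean and sample
#' standard deviation (n - 1 denominator, the figure-legend convention).
#' Groups of one report `sd = NA`.
#'
#' @param per_cell data.frame with a `condition` column.
#' @param metrics character vector of metric column names (default: all
#'   numeric columns).
#' @return data.frame with columns `condition`, `metric`, `n`, `mean`, `sd`.
#' @export
summarize_condition <- function(per_cell,
                                metrics = NULL) {
  if (!nrow(per_cell)) return(data.frame())
  if (is.null(metrics))
    metrics <- names(per_cell)[vapply(per_cell, is.numeric, logical(1))]
  metrics <- intersect(metrics, names(per_cell))
  metrics <- metrics[vapply(per_cell[metrics], is.numeric, logical(1))]
  rows <- list()
  for (cond in unique(per_cell$condition)) {
    sub <- per_cell[per_cell$condition == cond, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]; v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, metric = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
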