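# Minimal baseline TIFF codec: uncompressed, grayscale, single sample per
# pixel, 8/16/32-bit unsigned or 32/64-bit float, multi-page; reads both
# byte orders, writes little-endian with one strip per page. No TIFF-capable
# package exists in the target environment, so this is deliberately small
# and is gated by byte-level round-trip tests.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

read_tiff_entry_values <- function(con, type, count, raw4, endian) {
  size <- .tiff_type_size[[as.character(type)]]
  nbytes <- size * count
  if (nbytes <= 4L) {
    buf <- raw4[seq_len(nbytes)]
  } else {
    off <- read_u32(raw4, 1L, endian)
    old <- seek(con, where = NA)
    seek(con, off)
    buf <- readBin(con, "raw", nbytes)
    seek(con, old)
  }
  if (type %in% c(3L)) {          # SHORT
    vapply(seq_len(count), function(i)
      read_u16(buf, (i - 1L) * 2L + 1L, endian), numeric(1))
  } else if (type %in% c(4L)) {   # LONG
    vapply(seq_len(count), function(i)
      read_u32(buf, (i - 1L) * 4L + 1L, endian), numeric(1))
  } else if (type == 1L) {        # BYTE
    as.numeric(buf[seq_len(count)])
  } else {
    NULL                          # types we do not need
  }
}

read_u16 <- function(raw, at, endian) {
  b <- as.integer(raw[at:(at + 1L)])
  if (endian == "little") b[1L] + 256 * b[2L] else b[2L] + 256 * b[1L]
}

read_u32 <- function(raw, at, endian) {
  b <- as.integer(raw[at:(at + 3L)])
  if (endian == "big") b <- rev(b)
  b[1L] + 256 * (b[2L] + 256 * (b[3L] + 256 * b[4L]))
}

# Read all pages of a TIFF as a list of numeric matrices (row-major planes).
read_tiff_planes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 8L)
  endian <- if (identical(as.integer(hdr[1:2]), c(73L, 73L))) "little"
            else if (identical(as.integer(hdr[1:2]), c(77L, 77L))) "big"
            else stop("not a TIFF file: ", path)
  if (read_u16(hdr, 3L, endian) != 42) stop("bad TIFF magic in ", path)
  ifd_off <- read_u32(hdr, 5L, endian)
  planes <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_entries <- read_u16(readBin(con, "raw", 2L), 1L, endian)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- readBin(con, "raw", 12L)
      tag <- read_u16(e, 1L, endian)
      type <- read_u16(e, 3L, endian)
      count <- read_u32(e, 5L, endian)
      tags[[as.character(tag)]] <-
        read_tiff_entry_values(con, type, count, e[9:12], endian)
    }
    next_off_raw <- readBin(con, "raw", 4L)
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    if (is.null(W) || is.null(H)) stop("TIFF page missing dimensions")
    bits <- g(258, 8)[1L]
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    if (g(277, 1) != 1) stop("only single-sample (grayscale) TIFF supported")
    fmt <- g(339, 1)[1L]   # 1 = unsigned int, 3 = IEEE float
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    rows_per_strip <- g(278, H)
    raw_all <- raw(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      nb <- if (!is.null(counts)) counts[s] else
        ceiling(min(rows_per_strip, H) * W * bits / 8)
      raw_all <- c(raw_all, readBin(con, "raw", nb))
    }
    n <- W * H
    vals <- if (fmt == 3) {
      readBin(raw_all, "double", n, size = bits / 8, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(raw_all, "integer", n, size = 1L, signed = FALSE,
                         endian = endian))
    } else if (bits == 16L) {
      as.numeric(readBin(raw_all, "integer", n, size = 2L, signed = FALSE,
                         endian = endian))
    } else if (bits == 32L) {
      v <- readBin(raw_all, "integer", n, size = 4L, endian = endian)
      ifelse(v < 0, as.numeric(v) + 4294967296, as.numeric(v))
    } else stop("unsupported TIFF bit depth: ", bits)
    planes[[length(planes) + 1L]] <- matrix(vals, nrow = H, ncol = W,
                                            byrow = TRUE)
    ifd_off <- read_u32(next_off_raw, 1L, endian)
  }
  planes
}

u16_bytes <- function(x) {
  x <- as.integer(round(x))
  as.raw(c(x %% 256L, x %/% 256L))
}

u32_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16_bytes(tag), u16_bytes(type), u32_bytes(count), value_raw4)
}

# Write numeric matrices as a multi-page little-endian TIFF.
# dtype: "uint8", "uint16", "uint32", "float32", "float64".
write_tiff_planes <- function(planes, path, dtype = "float64") {
  stopifnot(is.list(planes), length(planes) >= 1L)
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, uint32 = 32L,
                 float32 = 32L, float64 = 64L,
                 stop("unsupported dtype: ", dtype))
  fmt <- if (grepl("^float", dtype)) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  n_pages <- length(planes)
  n_entries_per_ifd <- 10L
  ifd_size <- 2 + 12 * n_entries_per_ifd + 4
  page_bytes <- vapply(planes, function(m) nrow(m) * ncol(m) * bits / 8,
                       numeric(1))
  # layout: header, then per page [pixel data][IFD]
  data_offs <- 8 + cumsum(c(0, (page_bytes + ifd_size)[-n_pages]))
  ifd_offs <- data_offs + page_bytes
  writeBin(c(as.raw(c(73L, 73L)), u16_bytes(42L), u32_bytes(ifd_offs[1L])),
           con)
  for (p in seq_len(n_pages)) {
    m <- planes[[p]]
    stopifnot(is.matrix(m))
    H <- nrow(m); W <- ncol(m)
    v <- as.numeric(t(m))                 # row-major
    data_off <- data_offs[p]
    nbytes <- page_bytes[p]
    if (fmt == 3L) {
      writeBin(v, con, size = bits / 8, endian = "little")
    } else if (bits == 8L) {
      writeBin(as.raw(round(v)), con)
    } else if (bits == 16L) {
      iv <- as.integer(round(v))
      writeBin(as.raw(as.vector(rbind(iv %% 256L, iv %/% 256L))), con)
    } else {
      writeBin(as.raw(as.vector(vapply(round(v), function(x)
        u32_bytes(x), raw(4)))), con)
    }
    entries <- list(
      tiff_entry(256L, 4L, 1L, u32_bytes(W)),
      tiff_entry(257L, 4L, 1L, u32_bytes(H)),
      tiff_entry(258L, 3L, 1L, c(u16_bytes(bits), as.raw(c(0L, 0L)))),
      tiff_entry(259L, 3L, 1L, c(u16_bytes(1L), as.raw(c(0L, 0L)))),
      tiff_entry(262L, 3L, 1L, c(u16_bytes(1L), as.raw(c(0L, 0L)))),
      tiff_entry(273L, 4L, 1L, u32_bytes(data_off)),
      tiff_entry(277L, 3L, 1L, c(u16_bytes(1L), as.raw(c(0L, 0L)))),
      tiff_entry(278L, 4L, 1L, u32_bytes(H)),
      tiff_entry(279L, 4L, 1L, u32_bytes(nbytes)),
      tiff_entry(339L, 3L, 1L, c(u16_bytes(fmt), as.raw(c(0L, 0L))))
    )
    stopifnot(length(entries) == n_entries_per_ifd)
    next_ifd <- if (p < n_pages) ifd_offs[p + 1L] else 0
    writeBin(u16_bytes(length(entries)), con)
    for (e in entries) writeBin(e, con)
    writeBin(u32_bytes(next_ifd), con)
  }
  invisible(path)
}

#' Read a multi-channel TIFF image
#'
#' Reads a single- or multi-page grayscale TIFF and names the pages. Pixel
#' values are kept in their stored units (cast to double, never rescaled).
#'
#' @param path TIFF file path.
#' @param channel_names character vector, one name per page.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return an [mc_image()].
#' @export
read_image <- function(path, channel_names, pixel_size_um = 0.107) {
  planes <- read_tiff_planes(path)
  if (length(planes) != length(channel_names))
    stop("channel-count mismatch: file has ", length(planes),
         " page(s) but ", length(channel_names), " name(s) given")
  names(planes) <- channel_names
  mc_image(planes, pixel_size_um = pixel_size_um)
}

#' Write a multi-channel image to TIFF
#'
#' @param image an [mc_image()] or a named list of matrices.
#' @param path output path.
#' @param dtype `"auto"` picks `uint16` when every value is an integer in
#'   \[0, 65535\], else `float64` (bit-exact for doubles); or force one of
#'   `"uint8"`, `"uint16"`, `"uint32"`, `"float32"`, `"float64"`.
#' @return the path, invisibly.
#' @export
write_image <- function(image, path, dtype = "auto") {
  planes <- if (inherits(image, "mc_image")) image$channels
            else if (is.list(image)) image else list(image)
  if (dtype == "auto") {
    v <- unlist(lapply(planes, as.numeric), use.names = FALSE)
    dtype <- if (all(v == round(v)) && all(v >= 0) && all(v <= 65535))
      "uint16" else "float64"
  }
  write_tiff_planes(planes, path, dtype)
}

#' Read a binary mask from TIFF
#'
#' First page; nonzero pixels are true.
#' @param path TIFF path.
#' @return binary mask.
#' @export
read_mask <- function(path) {
  binary_mask(read_tiff_planes(path)[[1L]] != 0)
}

#' Write a binary mask as 8-bit TIFF (0 / 255)
#' @param mask binary mask.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  write_tiff_planes(list(ifelse(m, 255, 0)), path, "uint8")
}

# Even-odd scanline fill of one polygon given vertex (row, col) coordinates
# on the stated grid convention (0-based pixel centers at integers).
rasterize_polygon <- function(rows, cols, shape) {
  stopifnot(length(rows) == length(cols), length(rows) >= 3L)
  H <- shape[1L]; W <- shape[2L]
  out <- matrix(FALSE, H, W)
  n <- length(rows)
  r2 <- c(rows[-1L], rows[1L]); c2 <- c(cols[-1L], cols[1L])
  for (y in 0:(H - 1L)) {
    crosses <- (rows <= y) != (r2 <= y)
    if (!any(crosses)) next
    xs <- cols[crosses] + (y - rows[crosses]) *
      (c2[crosses] - cols[crosses]) / (r2[crosses] - rows[crosses])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- ceiling(xs[k]); b <- floor(xs[k + 1L])
      a <- max(a, 0); b <- min(b, W - 1L)
      if (a <= b) out[y + 1L, (a + 1L):(b + 1L)] <- TRUE
    }
  }
  binary_mask(out)
}

#' Read polygon ROIs from CSV and rasterize
#'
#' Expects columns `cell_id`, `vertex_index`, `row`, `col` (0-based pixel
#' coordinates); polygons are filled by even-odd scanline rule.
#'
#' @param path CSV path.
#' @param shape integer (height, width) of the target grid.
#' @return named list of binary masks, one per `cell_id`.
#' @export
read_polygon_roi <- function(path, shape) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "vertex_index", "row", "col")
  if (!all(need %in% names(df)))
    stop("polygon CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(df$cell_id)) {
    sub <- df[df$cell_id == id, ]
    sub <- sub[order(sub$vertex_index), ]
    out[[as.character(id)]] <- rasterize_polygon(sub$row, sub$col, shape)
  }
  out
}
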